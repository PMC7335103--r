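#' Aridity index from net radiation and precipitation
#'
#' Net radiation is first expressed as an equivalent evaporation depth
#' using the latent heat of vaporisation (lambda = 2.45 MJ/kg, typical of
#' ~20 degrees C):
#' `E (mm/day) = Rn (W/m^2) * 86400 / lambda`,
#' since 1 kg of water over 1 m^2 is a 1 mm depth. The aridity index is
#' the ratio of the period means, `mean(E) / mean(P)`; values above 2 mark
#' arid cells, at or below 2 humid cells. Cells with non-positive mean
#' precipitation or negative mean net radiation are masked.
#'
#' @param net_radiation [monthly_field] in W/m^2.
#' @param precipitation [monthly_field] in mm/day.
#' @param period `c(start_year, end_year)`; default full record.
#' @param lambda latent heat of vaporisation in J/kg.
#' @return a [static_field] of the dimensionless aridity index.
#' @export
compute_aridity <- function(net_radiation, precipitation, period = NULL,
                            lambda = LAMBDA_VAPORISATION) {
  stopifnot(inherits(net_radiation, "monthly_field"),
            inherits(precipitation, "monthly_field"))
  if (!grids_identical(net_radiation$grid, precipitation$grid))
    stop("net radiation and precipitation grids differ")
  rn_mean <- longterm_mean(net_radiation, period)$values
  p_mean <- longterm_mean(precipitation, period)$values
  e_mean <- rn_mean * 86400 / lambda    # mm/day
  out <- e_mean / p_mean
  out[is.na(p_mean) | p_mean <= 0 | is.na(rn_mean) | rn_mean < 0] <- NA_real_
  static_field(out, net_radiation$grid, units = "dimensionless")
}

#' Humid/arid regime labels from the aridity index
#'
#' @param aridity [static_field] from [compute_aridity].
#' @param split regime boundary (default 2): `aridity > split` is arid,
#'   `<= split` humid.
#' @return a character matrix (`"humid"`/`"arid"`, `NA` where masked).
#' @export
aridity_regime <- function(aridity, split = 2) {
  a <- aridity$values
  out <- matrix(NA_character_, nrow(a), ncol(a))
  out[!is.na(a) & a > split] <- "arid"
  out[!is.na(a) & a <= split] <- "humid"
  out
}

#' Group event cells into temperature-by-aridity climate boxes
#'
#' Half-open binning `[lower, upper)` on long-term mean temperature and on
#' the aridity index. Cells falling outside the configured edges are
#' clamped into the outermost bin on that axis and counted in the overflow
#' report. Boxes with fewer than `min_box_size` member cells are flagged
#' `discarded` and excluded from composites.
#'
#' @param events a `fire_events` frame.
#' @param temperature_mean [static_field] of long-term mean temperature
#'   (degrees C).
#' @param aridity [static_field] of the aridity index.
#' @param temp_edges,aridity_edges increasing bin-edge vectors. The default
#'   aridity edges keep the humid/arid boundary 2 as a mandatory edge.
#' @param min_box_size minimum member count for a box to be retained
#'   (default 25).
#' @return a data frame of class `climate_boxes`: one row per box with
#'   `temp_lo`, `temp_hi`, `aridity_lo`, `aridity_hi`, `n`, `discarded`;
#'   attribute `membership` is an integer vector assigning each event row
#'   to its box row, and attribute `overflow` counts clamped cells.
#' @export
assign_boxes <- function(events, temperature_mean, aridity,
                         temp_edges = seq(0, 30, by = 5),
                         aridity_edges = c(0.5, 1, 2, 4, 8),
                         min_box_size = 25L) {
  stopifnot(inherits(events, "fire_events"))
  if (is.unsorted(temp_edges, strictly = TRUE) ||
      is.unsorted(aridity_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  ij <- cbind(events$lat_idx, events$lon_idx)
  tvals <- temperature_mean$values[ij]
  avals <- aridity$values[ij]
  if (anyNA(tvals) || anyNA(avals))
    stop("every event cell needs finite temperature and aridity")
  clamp_bin <- function(x, edges) {
    # half-open [lo, hi); outside values clamped into the edge bins
    b <- findInterval(x, edges, left.open = FALSE)   # 0..len(edges)
    overflow <- b == 0L | b == length(edges)
    b[b == 0L] <- 1L
    b[b == length(edges)] <- length(edges) - 1L
    list(bin = b, overflow = overflow)
  }
  tb <- clamp_bin(tvals, temp_edges)
  ab <- clamp_bin(avals, aridity_edges)
  ntb <- length(temp_edges) - 1L
  nab <- length(aridity_edges) - 1L
  box_id <- (ab$bin - 1L) * ntb + tb$bin
  boxes <- expand.grid(tbin = seq_len(ntb), abin = seq_len(nab))
  out <- data.frame(
    box = seq_len(ntb * nab),
    temp_lo = temp_edges[boxes$tbin], temp_hi = temp_edges[boxes$tbin + 1L],
    aridity_lo = aridity_edges[boxes$abin],
    aridity_hi = aridity_edges[boxes$abin + 1L],
    n = as.integer(tabulate(box_id, nbins = ntb * nab)))
  out$discarded <- out$n < min_box_size
  attr(out, "membership") <- box_id
  attr(out, "overflow") <- sum(tb$overflow | ab$overflow)
  class(out) <- c("climate_boxes", class(out))
  out
}
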