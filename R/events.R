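#' Select each cell's largest burned-area month
#'
#' Per grid cell, the event is the calendar month with the highest burned
#' area over the record, considering only months whose observed-area
#' fraction exceeds `min_obs_fraction` (poorly observed months are removed
#' from the maximisation, not the whole cell). Cells whose admissible
#' months all have zero burned area yield no event. Ties on the maximum are
#' broken toward the earliest month (deterministic).
#'
#' @param burned_area [monthly_field] of burned area (same units as
#'   `land_area`, typically km^2 per month).
#' @param observed_fraction [monthly_field] of the per-month observed-area
#'   fraction in `[0, 1]`.
#' @param land_area [static_field] of cell land area; cells with
#'   non-positive or missing land area are skipped.
#' @param min_obs_fraction months with observed fraction at or below this
#'   are excluded (default 0.8).
#' @return a data frame of class `fire_events`: one row per retained cell
#'   with `lat_idx`, `lon_idx`, `event_index` (month index), `event_year`,
#'   `event_month`, `burned_area`, `ba_fraction`.
#' @export
select_largest_events <- function(burned_area, observed_fraction, land_area,
                                  min_obs_fraction = 0.8) {
  stopifnot(inherits(burned_area, "monthly_field"),
            inherits(observed_fraction, "monthly_field"))
  if (!grids_identical(burned_area$grid, observed_fraction$grid) ||
      !identical(burned_area$start, observed_fraction$start) ||
      n_times(burned_area) != n_times(observed_fraction))
    stop("burned area and observed fraction must share grid and calendar")
  d <- dim(burned_area$values)
  ba <- burned_area$values
  ba[is.na(observed_fraction$values) |
       observed_fraction$values <= min_obs_fraction] <- NA_real_
  rows <- integer(); cols <- integer(); whens <- integer(); vals <- numeric()
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    la <- land_area$values[i, j]
    if (is.na(la) || la <= 0) next
    series <- ba[i, j, ]
    if (all(is.na(series))) next
    mx <- max(series, na.rm = TRUE)
    if (mx <= 0) next
    t0 <- which(series == mx)[1]      # earliest month on ties
    rows <- c(rows, i); cols <- c(cols, j); whens <- c(whens, t0)
    vals <- c(vals, mx)
  }
  ym <- index_to_ym(whens, burned_area$start)
  if (length(whens) == 1L)
    ym <- matrix(ym, 1L, 2L, dimnames = list(NULL, c("year", "month")))
  la <- land_area$values[cbind(rows, cols)]
  out <- data.frame(lat_idx = rows, lon_idx = cols, event_index = whens,
                    event_year = if (length(whens)) ym[, "year"] else integer(),
                    event_month = if (length(whens)) ym[, "month"] else integer(),
                    burned_area = vals,
                    ba_fraction = vals / la)
  attr(out, "start") <- burned_area$start
  attr(out, "n_times") <- d[3]
  class(out) <- c("fire_events", class(out))
  out
}

#' Population-density threshold over soil-moisture-available cells
#'
#' The empirical percentile (linear interpolation between order statistics,
#' the same quantile definition used for all composite statistics in this
#' package) of population density over the cells where soil moisture is
#' available — all such cells, not only the event cells.
#'
#' @param population [static_field] of population density (people/km^2).
#' @param sm_available logical matrix marking cells with any soil-moisture
#'   data.
#' @param percentile percentile in `[0, 100]` (default 25).
#' @return the density threshold (people/km^2).
#' @export
population_threshold <- function(population, sm_available, percentile = 25) {
  stopifnot(inherits(population, "static_field"), is.logical(sm_available))
  dens <- population$values[sm_available & !is.na(population$values)]
  if (!length(dens)) stop("no cells with available soil moisture")
  unname(stats::quantile(dens, percentile / 100, type = 7))
}

#' Apply the event filter cascade
#'
#' An event survives iff (a) every monthly soil-moisture anomaly from
#' `window[1]` to `window[2]` months around the event is unmasked (a window
#' reaching outside the record fails this filter), (b) the cell's long-term
#' mean temperature is at least `temp_min`, and (c) the cell's population
#' density is strictly below the `pop_percentile`-th percentile of density
#' over all soil-moisture-available cells. Survival is a conjunction and
#' order-independent; the removal counts in the report attribute each lost
#' event to its first failing filter in the order window -> temperature ->
#' population.
#'
#' @param events a `fire_events` frame from [select_largest_events].
#' @param sm_anomaly soil-moisture [normalize_anomaly] field on the event
#'   grid.
#' @param temperature_mean [static_field] of long-term mean temperature
#'   (degrees C).
#' @param population [static_field] of population density; `NULL` disables
#'   filter (c).
#' @param window integer `c(before, after)` in months relative to the event
#'   (default `c(-5, 1)`).
#' @param temp_min cold-cell threshold in degrees C (default 0).
#' @param pop_percentile percentile for the population cut (default 25);
#'   100 disables the cut.
#' @return the surviving events, with attributes `report` (a data frame of
#'   per-stage removal counts) and `pop_threshold`.
#' @export
filter_events <- function(events, sm_anomaly, temperature_mean,
                          population = NULL, window = c(-5L, 1L),
                          temp_min = 0, pop_percentile = 25) {
  stopifnot(inherits(events, "fire_events"),
            inherits(sm_anomaly, "monthly_field"))
  n <- nrow(events)
  lags <- seq.int(window[1], window[2])
  win_ok <- vapply(seq_len(n), function(e) {
    t_idx <- events$event_index[e] + lags
    if (any(t_idx < 1L | t_idx > n_times(sm_anomaly))) return(FALSE)
    !anyNA(sm_anomaly$values[events$lat_idx[e], events$lon_idx[e], t_idx])
  }, logical(1))
  tmean <- temperature_mean$values[cbind(events$lat_idx, events$lon_idx)]
  temp_ok <- !is.na(tmean) & tmean >= temp_min
  if (is.null(population) || pop_percentile >= 100) {
    pop_ok <- rep(TRUE, n)
    thr <- NA_real_
  } else {
    sm_avail <- apply(!is.na(sm_anomaly$values), 1:2, any)
    thr <- population_threshold(population, sm_avail, pop_percentile)
    dens <- population$values[cbind(events$lat_idx, events$lon_idx)]
    pop_ok <- !is.na(dens) & dens < thr
  }
  keep <- win_ok & temp_ok & pop_ok
  # first-failure attribution
  fail_window <- !win_ok
  fail_temp <- win_ok & !temp_ok
  fail_pop <- win_ok & temp_ok & !pop_ok
  report <- data.frame(
    stage = c("candidates", "removed_window", "removed_temperature",
              "removed_population", "retained"),
    count = c(n, sum(fail_window), sum(fail_temp), sum(fail_pop), sum(keep)))
  out <- events[keep, , drop = FALSE]
  attr(out, "start") <- attr(events, "start")
  attr(out, "n_times") <- attr(events, "n_times")
  attr(out, "report") <- report
  attr(out, "pop_threshold") <- thr
  class(out) <- c("fire_events", "data.frame")
  out
}
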