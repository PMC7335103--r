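#' Aggregate a daily field to monthly means
#'
#' Monthly value = arithmetic mean of the valid (non-missing) daily values
#' in that calendar month; the month is masked when fewer than `min_days`
#' valid days are available, following the data-quality rule used for the
#' satellite soil-moisture and VOD products.
#'
#' @param daily a [daily_field].
#' @param min_days minimum number of valid days for a monthly mean
#'   (default 15).
#' @return a [monthly_field] covering the calendar months spanned by
#'   `daily$dates`.
#' @export
daily_to_monthly <- function(daily, min_days = 15L) {
  stopifnot(inherits(daily, "daily_field"))
  if (min_days > 31L) stop("min_days exceeds the length of any month")
  yr <- as.integer(format(daily$dates, "%Y"))
  mo <- as.integer(format(daily$dates, "%m"))
  start <- c(yr[1], mo[1])
  idx <- ym_to_index(yr, mo, start)
  nmonths <- max(idx)
  nlat <- dim(daily$values)[1]; nlon <- dim(daily$values)[2]
  vals <- array(NA_real_, c(nlat, nlon, nmonths))
  for (t in seq_len(nmonths)) {
    slab <- daily$values[, , idx == t, drop = FALSE]
    n_ok <- rowSums(!is.na(slab), dims = 2)
    if (min_days > dim(slab)[3])
      stop(sprintf("min_days (%d) exceeds the %d days of month %d",
                   min_days, dim(slab)[3], t))
    m <- rowMeans(slab, na.rm = TRUE, dims = 2)
    m[n_ok < min_days] <- NA_real_
    vals[, , t] <- m
  }
  monthly_field(vals, daily$grid, start, units = daily$units)
}

#' Regrid a field to a target grid
#'
#' Two methods: `"cell-average"` takes the mean of the source cells whose
#' centers fall inside each target cell (mask-aware; empty target cells are
#' masked), and requires the target to be at least as coarse as the source;
#' `"nearest"` takes the value of the source cell containing each target
#' cell center (the natural choice when refining, e.g. a 0.5 degree
#' population layer onto the 0.25 degree analysis grid).
#'
#' @param field a [monthly_field] or [static_field].
#' @param target an [fc_grid].
#' @param method `"cell-average"` or `"nearest"`.
#' @return the field on `target`.
#' @export
regrid <- function(field, target, method = c("cell-average", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(target, "fc_grid"))
  src <- field$grid
  if (grids_identical(src, target)) return(field)
  if (method == "cell-average" && target$cell_size < src$cell_size - 1e-9)
    stop("cell-average regridding requires a target at least as coarse as the source")
  is_static <- inherits(field, "static_field")
  nt <- if (is_static) 1L else n_times(field)
  src_vals <- if (is_static) array(field$values, c(dim(field$values), 1L))
              else field$values
  out <- array(NA_real_,
               c(length(target$lat), length(target$lon), nt))
  if (method == "nearest") {
    # index of the source cell containing each target center
    pick <- function(centers_src, x, half)
      vapply(x, function(v) {
        i <- which(abs(centers_src - v) <= half + 1e-9)
        if (length(i)) i[which.min(abs(centers_src[i] - v))] else NA_integer_
      }, integer(1))
    li <- pick(src$lat, target$lat, src$cell_size / 2)
    lj <- pick(src$lon, target$lon, src$cell_size / 2)
    for (t in seq_len(nt))
      out[, , t] <- src_vals[li, lj, t]
  } else {
    # target-cell membership of each source center (half-open cells)
    bin <- function(centers_src, centers_tgt, half) {
      lo <- centers_tgt - half
      hi <- centers_tgt + half
      vapply(centers_src, function(v) {
        i <- which(v >= lo - 1e-9 & v < hi - 1e-9)
        if (length(i)) i[1] else NA_integer_
      }, integer(1))
    }
    bi <- bin(src$lat, target$lat, target$cell_size / 2)
    bj <- bin(src$lon, target$lon, target$cell_size / 2)
    for (t in seq_len(nt)) {
      sl <- src_vals[, , t]
      for (i in seq_along(target$lat)) {
        rows <- which(bi == i)
        if (!length(rows)) next
        for (j in seq_along(target$lon)) {
          cols <- which(bj == j)
          if (!length(cols)) next
          block <- sl[rows, cols]
          if (any(!is.na(block)))
            out[i, j, t] <- mean(block, na.rm = TRUE)
        }
      }
    }
  }
  if (is_static)
    static_field(out[, , 1, drop = TRUE], target, field$units)
  else
    monthly_field(out, target, field$start, field$units)
}

#' Month-of-year climatology (mean and standard deviation)
#'
#' Per cell and month-of-year, the mean and sample standard deviation
#' (n - 1 denominator) over the valid years inside the reference period.
#' Cells with fewer than 2 valid years for a month-of-year, or zero
#' standard deviation, are masked so they can never yield infinite
#' z-scores.
#'
#' @param field a [monthly_field].
#' @param period integer `c(start_year, end_year)` of the reference period;
#'   defaults to the years fully spanned by the field.
#' @return a list of class `climatology_stats` with `mean`, `sd`, `n`
#'   (arrays `(n_lat, n_lon, 12)`), `period` and the field's `grid`/`start`.
#' @export
monthly_climatology <- function(field, period = NULL) {
  stopifnot(inherits(field, "monthly_field"))
  nt <- n_times(field)
  ym <- index_to_ym(seq_len(nt), field$start)
  if (is.null(period)) period <- range(ym[, "year"])
  if (diff(period) + 1 < 2) stop("reference period must span at least 2 years")
  in_period <- ym[, "year"] >= period[1] & ym[, "year"] <= period[2]
  moy <- index_to_moy(seq_len(nt), field$start)
  d <- dim(field$values)
  mean_a <- array(NA_real_, c(d[1], d[2], 12))
  sd_a <- array(NA_real_, c(d[1], d[2], 12))
  n_a <- array(0L, c(d[1], d[2], 12))
  for (m in 1:12) {
    sel <- which(in_period & moy == m)
    if (!length(sel)) next
    slab <- field$values[, , sel, drop = FALSE]
    n <- rowSums(!is.na(slab), dims = 2)
    mu <- rowMeans(slab, na.rm = TRUE, dims = 2)
    # sample sd with the n-1 denominator
    ss <- rowSums(sweep(slab, 1:2, mu)^2, na.rm = TRUE, dims = 2)
    sd <- sqrt(ss / pmax(n - 1L, 1L))
    bad <- n < 2L | sd == 0
    mu[bad] <- NA_real_
    sd[bad] <- NA_real_
    mean_a[, , m] <- mu
    sd_a[, , m] <- sd
    n_a[, , m] <- n
  }
  structure(list(mean = mean_a, sd = sd_a, n = n_a,
                 period = as.integer(period), grid = field$grid),
            class = "climatology_stats")
}

#' Month-of-year z-score anomalies
#'
#' `z(t, cell) = (x(t, cell) - mean[moy(t), cell]) / sd[moy(t), cell]`,
#' masked wherever the input or the climatology is masked. By construction,
#' over the reference period each cell's z-series has mean 0 and sample
#' standard deviation 1 for every month-of-year with valid climatology.
#'
#' @param field a [monthly_field].
#' @param clim a `climatology_stats` from [monthly_climatology] on a
#'   compatible grid.
#' @return a [monthly_field] of dimensionless z-scores (class also
#'   `anomaly_field`).
#' @export
normalize_anomaly <- function(field, clim) {
  stopifnot(inherits(field, "monthly_field"),
            inherits(clim, "climatology_stats"))
  if (!grids_identical(field$grid, clim$grid))
    stop("field and climatology grids differ")
  nt <- n_times(field)
  moy <- index_to_moy(seq_len(nt), field$start)
  z <- array(NA_real_, dim(field$values))
  for (t in seq_len(nt)) {
    sd_t <- clim$sd[, , moy[t]]
    if (any(!is.na(sd_t) & sd_t == 0))
      stop("internal error: unmasked zero climatological sd")
    z[, , t] <- (field$values[, , t] - clim$mean[, , moy[t]]) / sd_t
  }
  out <- monthly_field(z, field$grid, field$start, units = "z-score")
  class(out) <- c("anomaly_field", class(out))
  out
}

#' Long-term mean of a monthly field over a period
#'
#' Ignores masked months; used for the cold-cell temperature filter and
#' the aridity index.
#'
#' @param field a [monthly_field].
#' @param period `c(start_year, end_year)`; default full record.
#' @return a [static_field] of period means.
#' @export
longterm_mean <- function(field, period = NULL) {
  stopifnot(inherits(field, "monthly_field"))
  nt <- n_times(field)
  ym <- index_to_ym(seq_len(nt), field$start)
  if (is.null(period)) period <- range(ym[, "year"])
  sel <- ym[, "year"] >= period[1] & ym[, "year"] <= period[2]
  m <- rowMeans(field$values[, , sel, drop = FALSE], na.rm = TRUE, dims = 2)
  m[!is.finite(m)] <- NA_real_
  static_field(m, field$grid, field$units)
}
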