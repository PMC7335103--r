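#' Admissible null months for one event
#'
#' The null months for an event are every record month whose month-of-year
#' lies within one month of the event's month-of-year (with December to
#' January wrap-around) and whose calendar year differs from the event
#' year. For an event in July 2010 on a 2001-2018 record this is
#' {Jun, Jul, Aug} x {2001..2018} minus the three 2010 months: 51 months,
#' each drawn with equal probability.
#'
#' @param event_year,event_month calendar year and month of the event.
#' @param start `c(year, month)` of month index 1.
#' @param n_times number of months in the record.
#' @return integer vector of admissible month indices.
#' @export
null_month_candidates <- function(event_year, event_month, start, n_times) {
  all_idx <- seq_len(n_times)
  ym <- index_to_ym(all_idx, start)
  moy <- ym[, "month"]
  moy_set <- (event_month + (-1:1) - 1L) %% 12L + 1L
  cand <- all_idx[moy %in% moy_set & ym[, "year"] != event_year]
  if (!length(cand))
    stop("no admissible null month (study period too short)")
  cand
}

#' Draw one same-season, different-year null month
#'
#' Uniform over the admissible months of [null_month_candidates]; uses the
#' current RNG stream.
#'
#' @inheritParams null_month_candidates
#' @return `c(year, month)` of the drawn month.
#' @export
sample_null_month <- function(event_year, event_month, start, n_times) {
  cand <- null_month_candidates(event_year, event_month, start, n_times)
  index_to_ym(cand[sample.int(length(cand), 1L)], start)
}

#' Composite specification for the resampling null
#'
#' Internal helper shared by the observed composite and the null band:
#' `groups` is a named list of integer event-row indices (boxes, regimes,
#' strata, or a single group of all events).
#' @noRd
composite_stat <- function(values_by_lag, groups) {
  # values_by_lag: matrix (n_events, n_lags); returns (n_groups, n_lags)
  out <- matrix(NA_real_, length(groups), ncol(values_by_lag))
  for (g in seq_along(groups)) {
    sub <- values_by_lag[groups[[g]], , drop = FALSE]
    # median() agrees with the type-7 quantile at p = 0.5
    out[g, ] <- apply(sub, 2, function(x)
      if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE))
  }
  out
}

#' Monte-Carlo null band for composite medians
#'
#' For each repetition, every event's month is independently replaced by a
#' random same-season (month-of-year within one month, December/January
#' wrapping), different-year month; the identical composite statistic (the
#' per-group median at each lag) is recomputed; and the per-cell empirical
#' percentiles over the repetitions form the band. The default 1,000
#' repetitions and (5, 95) percentile pair give the two-sided 90% level.
#'
#' @param anomalies an anomaly [monthly_field].
#' @param events a `fire_events` frame (filtered).
#' @param groups named list of integer vectors of event rows; each group
#'   yields one band row (e.g. climate boxes, humid/arid regimes, or
#'   `list(all = seq_len(nrow(events)))`).
#' @param lags integer lags of the composite.
#' @param n_boot repetitions (default 1000; fewer than 100 warns).
#' @param percentile_pair lower/upper band percentiles (default `c(5, 95)`).
#' @param rng_seed integer seed making the band reproducible; `NULL` uses
#'   the current RNG stream.
#' @return a list of class `null_band`: `lower`, `upper` (matrices
#'   `n_groups x n_lags`), `groups`, `lags`, `n_boot`, `percentile_pair`.
#' @export
null_band <- function(anomalies, events, groups, lags,
                      n_boot = 1000L, percentile_pair = c(5, 95),
                      rng_seed = NULL) {
  stopifnot(inherits(anomalies, "monthly_field"),
            inherits(events, "fire_events"), is.list(groups))
  if (percentile_pair[1] >= percentile_pair[2])
    stop("percentile pair must be increasing")
  if (n_boot < 100L)
    warning("n_boot < 100: percentile band estimates are unstable")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  start <- attr(events, "start")
  nt <- n_times(anomalies)
  lags <- as.integer(lags)
  n <- nrow(events)
  # pre-draw all null months: one matrix of month indices (event x rep)
  draws <- matrix(0L, n, n_boot)
  for (e in seq_len(n)) {
    cand <- null_month_candidates(events$event_year[e],
                                  events$event_month[e], start, nt)
    draws[e, ] <- cand[sample.int(length(cand), n_boot, replace = TRUE)]
  }
  stats <- array(NA_real_, c(n_boot, length(groups), length(lags)))
  vals <- matrix(NA_real_, n, length(lags))
  for (b in seq_len(n_boot)) {
    for (l in seq_along(lags)) {
      t_idx <- draws[, b] + lags[l]
      fi <- flat_index(anomalies, events$lat_idx, events$lon_idx, t_idx)
      ok <- !is.na(fi)
      vals[, l] <- NA_real_
      vals[ok, l] <- anomalies$values[fi[ok]]
    }
    stats[b, , ] <- composite_stat(vals, groups)
  }
  p <- percentile_pair / 100
  lower <- upper <- matrix(NA_real_, length(groups), length(lags))
  for (g in seq_along(groups)) for (l in seq_along(lags)) {
    s <- stats[, g, l]
    if (all(is.na(s))) next
    q <- fc_quantile(s, p)
    lower[g, l] <- q[1]; upper[g, l] <- q[2]
  }
  dimnames(lower) <- dimnames(upper) <-
    list(names(groups), paste0("lag", lags))
  structure(list(lower = lower, upper = upper, groups = groups,
                 lags = lags, n_boot = n_boot,
                 percentile_pair = percentile_pair),
            class = "null_band")
}

#' Flag composite cells outside the null band
#'
#' Significant iff the observed statistic lies strictly below the lower or
#' strictly above the upper band bound; an observed value exactly on a
#' bound is not significant. Masked where either input is masked.
#'
#' @param observed matrix of observed composite medians, `n_groups x
#'   n_lags` matching the band.
#' @param band a `null_band`.
#' @return logical matrix of the same shape.
#' @export
flag_significant <- function(observed, band) {
  stopifnot(inherits(band, "null_band"))
  observed <- as.matrix(observed)
  if (!all(dim(observed) == dim(band$lower)))
    stop("observed composite and band shapes differ")
  out <- observed < band$lower | observed > band$upper
  out[is.na(observed) | is.na(band$lower) | is.na(band$upper)] <- NA
  out
}
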