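#' Event-relative lag matrix
#'
#' Entry `(e, l)` is the anomaly at `event_time(e) + lags[l]` calendar
#' months in the event's cell; entries whose month falls outside the record
#' are masked (`NA`) rather than dropping the event from other lags.
#'
#' @param anomalies an anomaly [monthly_field] (or any monthly field).
#' @param events a `fire_events` frame on the same grid and calendar.
#' @param lags ordered integer vector of whole-month offsets (lag 0 is the
#'   event month; negative lags precede it).
#' @return a numeric matrix `(n_events, n_lags)` with `dimnames` on the
#'   lag axis; class `lag_matrix`, attribute `lags`.
#' @export
event_lag_matrix <- function(anomalies, events, lags = -12:6) {
  stopifnot(inherits(anomalies, "monthly_field"),
            inherits(events, "fire_events"))
  if (nrow(events) == 0L) stop("empty event set")
  lags <- as.integer(lags)
  n <- nrow(events)
  out <- matrix(NA_real_, n, length(lags),
                dimnames = list(NULL, paste0("lag", lags)))
  for (l in seq_along(lags)) {
    t_idx <- events$event_index + lags[l]
    fi <- flat_index(anomalies, events$lat_idx, events$lon_idx, t_idx)
    ok <- !is.na(fi)
    out[ok, l] <- anomalies$values[fi[ok]]
  }
  attr(out, "lags") <- lags
  class(out) <- c("lag_matrix", class(out))
  out
}

# linear-interpolation quantiles (R type 7), the single definition used for
# medians, interquartile bounds and the population threshold
fc_quantile <- function(x, p) {
  x <- x[!is.na(x)]
  if (!length(x)) return(rep(NA_real_, length(p)))
  unname(stats::quantile(x, p, type = 7))
}

#' Composite median and interquartile range per lag
#'
#' Per lag, the median and interquartile bounds over the unmasked entries
#' of the chosen event subset, with the number of contributing events.
#' Lags whose entries are all masked yield masked statistics.
#'
#' @param matrix a `lag_matrix` from [event_lag_matrix].
#' @param subset integer or logical index of event rows (default all).
#' @return a data frame of class `composite_series` with columns `lag`,
#'   `median`, `q25`, `q75`, `n`.
#' @export
composite_median <- function(matrix, subset = NULL) {
  stopifnot(inherits(matrix, "lag_matrix"))
  m <- if (is.null(subset)) matrix else matrix[subset, , drop = FALSE]
  if (nrow(m) == 0L) stop("empty event subset")
  lags <- attr(matrix, "lags")
  qs <- t(apply(m, 2, fc_quantile, p = c(0.25, 0.5, 0.75)))
  out <- data.frame(lag = lags, median = qs[, 2], q25 = qs[, 1],
                    q75 = qs[, 3], n = as.integer(colSums(!is.na(m))))
  rownames(out) <- NULL
  class(out) <- c("composite_series", class(out))
  out
}

#' Per-climate-box composite median at one lag
#'
#' For each retained (non-discarded) box, the median of the lag-matrix
#' entries of its member events at the given lag.
#'
#' @param matrix a `lag_matrix`.
#' @param boxes a `climate_boxes` frame from [assign_boxes] built on the
#'   same events.
#' @param lag a single lag present in the matrix.
#' @return a data frame: one row per retained box with the box bounds,
#'   `median` and `n` (contributing, unmasked events).
#' @export
box_composites_at_lag <- function(matrix, boxes, lag) {
  stopifnot(inherits(matrix, "lag_matrix"), inherits(boxes, "climate_boxes"))
  lags <- attr(matrix, "lags")
  l <- match(as.integer(lag), lags)
  if (is.na(l)) stop("lag not present in lag matrix")
  membership <- attr(boxes, "membership")
  keep <- which(!boxes$discarded)
  med <- vapply(keep, function(b)
    fc_quantile(matrix[membership == b, l], 0.5), numeric(1))
  n_ok <- vapply(keep, function(b)
    sum(!is.na(matrix[membership == b, l])), numeric(1))
  out <- boxes[keep, c("box", "temp_lo", "temp_hi", "aridity_lo",
                       "aridity_hi")]
  out$lag <- rep(as.integer(lag), length(keep))
  out$median <- med
  out$n <- as.integer(n_ok)
  rownames(out) <- NULL
  out
}

#' Stratify events by burned-area size or population density
#'
#' Either equal-count quantile groups (default quartiles: 0-25, 25-50,
#' 50-75, 75-100th percentiles, half-open on the left except the first
#' group) or explicit half-open bin edges. Groups are disjoint and
#' exhaustive. A degenerate key (all values equal) collapses to a single
#' group with a warning.
#'
#' @param events a `fire_events` frame.
#' @param key numeric vector of the stratification key, one value per
#'   event (e.g. `events$ba_fraction`, or population density looked up at
#'   the event cells).
#' @param scheme `"quartiles"` for equal-count quartiles, or a numeric
#'   vector of explicit increasing bin edges.
#' @return an integer group label per event (1 = lowest), with attribute
#'   `breaks` and attribute `labels` (human-readable ranges).
#' @export
stratify <- function(events, key, scheme = "quartiles") {
  stopifnot(inherits(events, "fire_events"), length(key) == nrow(events),
            !anyNA(key))
  if (identical(scheme, "quartiles")) {
    br <- fc_quantile(key, c(0, 0.25, 0.5, 0.75, 1))
    if (length(unique(br)) < 2L) {
      warning("degenerate stratification key: all values equal; one group")
      g <- rep(1L, length(key))
      attr(g, "breaks") <- range(key)
      attr(g, "labels") <- "all"
      return(g)
    }
    br <- unique(br)
    g <- findInterval(key, br, rightmost.closed = TRUE, left.open = FALSE)
  } else {
    br <- as.numeric(scheme)
    if (is.unsorted(br, strictly = TRUE))
      stop("explicit bin edges must be strictly increasing")
    # half-open [lo, hi) bins, except the top bin which closes at the
    # last edge so a key exactly at the maximum is not lost
    g <- findInterval(key, br, rightmost.closed = TRUE, left.open = FALSE)
    if (any(g == 0L | g == length(br)))
      stop("key values fall outside the explicit bin edges")
  }
  labels <- sprintf("[%.4g, %.4g%s", br[-length(br)], br[-1],
                    c(rep(")", length(br) - 2L), "]"))
  g <- as.integer(g)
  attr(g, "breaks") <- br
  attr(g, "labels") <- labels
  g
}
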