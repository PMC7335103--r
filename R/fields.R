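#' Regular latitude-longitude grid
#'
#' Constructs the grid descriptor shared by all gridded fields: cell-center
#' coordinates along each axis plus the (square) cell size in degrees.
#' Coordinates must be equally spaced with spacing equal to `cell_size`.
#'
#' @param lat,lon numeric vectors of cell-center coordinates (degrees),
#'   strictly increasing and equally spaced.
#' @param cell_size cell edge length in degrees.
#' @return an object of class `fc_grid`.
#' @export
fc_grid <- function(lat, lon, cell_size) {
  stopifnot(is.numeric(lat), is.numeric(lon), length(lat) >= 1,
            length(lon) >= 1, cell_size > 0)
  chk <- function(x) length(x) < 2 ||
    all(abs(diff(x) - cell_size) < 1e-8)
  if (!chk(lat) || !chk(lon))
    stop("grid coordinates must be equally spaced at cell_size")
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 cell_size = cell_size),
            class = "fc_grid")
}

#' @export
print.fc_grid <- function(x, ...) {
  cat(sprintf("<fc_grid> %d x %d cells of %.4g deg, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              length(x$lat), length(x$lon), x$cell_size,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Monthly gridded field
#'
#' A contiguous monthly time series on a regular grid. Missing data are
#' stored as `NA`; the missingness mask is therefore `is.na(values)`.
#' The time axis is implicit: month `t` (1-based) is `start` plus `t - 1`
#' calendar months, with no skipped months.
#'
#' @param values numeric array with dim `(n_lat, n_lon, n_time)`. Non-finite
#'   entries are coerced to `NA`.
#' @param grid an [fc_grid].
#' @param start integer vector `c(year, month)` of the first time slice.
#' @param units free-text unit string carried through I/O.
#' @return an object of class `monthly_field`.
#' @export
monthly_field <- function(values, grid, start, units = "") {
  stopifnot(inherits(grid, "fc_grid"), length(dim(values)) == 3,
            length(start) == 2, start[2] >= 1, start[2] <= 12)
  d <- dim(values)
  if (d[1] != length(grid$lat) || d[2] != length(grid$lon))
    stop("values dims do not match grid")
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, grid = grid,
                 start = as.integer(start), units = units),
            class = "monthly_field")
}

#' @export
print.monthly_field <- function(x, ...) {
  n <- dim(x$values)[3]
  e <- index_to_ym(n, x$start)
  cat(sprintf("<monthly_field> %d x %d x %d months (%d-%02d .. %d-%02d), %.1f%% missing\n",
              dim(x$values)[1], dim(x$values)[2], n,
              x$start[1], x$start[2], e[1], e[2],
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Daily gridded field
#'
#' Same layout as [monthly_field] but with a `Date` vector along the third
#' dimension (consecutive days).
#'
#' @param values numeric array with dim `(n_lat, n_lon, n_days)`.
#' @param grid an [fc_grid].
#' @param dates `Date` vector, consecutive, one per time slice.
#' @param units unit string.
#' @return an object of class `daily_field`.
#' @export
daily_field <- function(values, grid, dates, units = "") {
  stopifnot(inherits(grid, "fc_grid"), length(dim(values)) == 3,
            inherits(dates, "Date"))
  d <- dim(values)
  if (d[3] != length(dates)) stop("dates length does not match time dim")
  if (d[1] != length(grid$lat) || d[2] != length(grid$lon))
    stop("values dims do not match grid")
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
    stop("dates must be consecutive days")
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, grid = grid, dates = dates, units = units),
            class = "daily_field")
}

#' Static (time-invariant) gridded field
#'
#' @param values numeric matrix `(n_lat, n_lon)`.
#' @param grid an [fc_grid].
#' @param units unit string.
#' @return an object of class `static_field`.
#' @export
static_field <- function(values, grid, units = "") {
  stopifnot(inherits(grid, "fc_grid"), is.matrix(values))
  if (nrow(values) != length(grid$lat) || ncol(values) != length(grid$lon))
    stop("values dims do not match grid")
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, grid = grid, units = units),
            class = "static_field")
}

n_times <- function(field) dim(field$values)[3]

# ---- calendar arithmetic (whole months, 1-based indices) -------------------

#' Month index of a calendar (year, month) relative to a field start
#'
#' @param year,month calendar year and month (vectors recycle).
#' @param start `c(year, month)` of index 1.
#' @return integer index (may fall outside the record; callers check range).
#' @export
ym_to_index <- function(year, month, start) {
  as.integer((year - start[1]) * 12L + (month - start[2]) + 1L)
}

#' Calendar (year, month) of a month index
#'
#' @param i 1-based month index (vectorised).
#' @param start `c(year, month)` of index 1.
#' @return for scalar `i` an integer `c(year, month)`; for vector `i` a
#'   two-column matrix.
#' @export
index_to_ym <- function(i, start) {
  m0 <- (start[1] * 12L + (start[2] - 1L)) + (as.integer(i) - 1L)
  out <- cbind(year = m0 %/% 12L, month = m0 %% 12L + 1L)
  if (length(i) == 1L) out[1L, ] else out
}

#' Month-of-year (1..12) of each month index of a field
#'
#' @param i 1-based month index (vectorised).
#' @param start `c(year, month)` of index 1.
#' @return integer vector in 1..12.
#' @export
index_to_moy <- function(i, start) {
  as.integer((start[2] - 1L + as.integer(i) - 1L) %% 12L + 1L)
}

# flat index into the (lat, lon, time) cube; NA where t out of range
flat_index <- function(field, lat_idx, lon_idx, t_idx) {
  d <- dim(field$values)
  n <- length(t_idx)
  lat_idx <- rep_len(as.integer(lat_idx), n)
  lon_idx <- rep_len(as.integer(lon_idx), n)
  ok <- !is.na(t_idx) & t_idx >= 1L & t_idx <= d[3]
  out <- rep(NA_integer_, length(t_idx))
  out[ok] <- lat_idx[ok] + (lon_idx[ok] - 1L) * d[1] +
    (t_idx[ok] - 1L) * d[1] * d[2]
  out
}
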