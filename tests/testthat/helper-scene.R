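# shared fixtures built in code; the moderate scene is generated once per
# test run and reused across files
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

mk_grid <- function(nlat, nlon, cs = 0.25) {
  fc_grid(lat = 10 + cs * (seq_len(nlat) - 0.5),
          lon = 5 + cs * (seq_len(nlon) - 0.5),
          cell_size = cs)
}

mk_monthly <- function(values, nlat = 1, nlon = 1, start = c(2001, 1),
                       grid = NULL) {
  if (is.null(dim(values)))
    values <- array(values, c(nlat, nlon, length(values) / (nlat * nlon)))
  if (is.null(grid)) grid <- mk_grid(dim(values)[1], dim(values)[2])
  monthly_field(values, grid, start)
}

mk_static <- function(values, grid = NULL) {
  values <- as.matrix(values)
  if (is.null(grid)) grid <- mk_grid(nrow(values), ncol(values))
  static_field(values, grid)
}

# build a fire_events frame by hand for unit tests
mk_events <- function(lat_idx, lon_idx, event_index, start = c(2001L, 1L),
                      n_times = 216L, ba_fraction = NULL) {
  ym <- index_to_ym(event_index, start)
  if (length(event_index) == 1L)
    ym <- matrix(ym, 1, 2, dimnames = list(NULL, c("year", "month")))
  out <- data.frame(lat_idx = as.integer(lat_idx),
                    lon_idx = as.integer(lon_idx),
                    event_index = as.integer(event_index),
                    event_year = ym[, "year"],
                    event_month = ym[, "month"],
                    ba_fraction = if (is.null(ba_fraction))
                      rep(0.1, length(event_index)) else ba_fraction)
  attr(out, "start") <- as.integer(start)
  attr(out, "n_times") <- as.integer(n_times)
  class(out) <- c("fire_events", "data.frame")
  out
}

# a moderate all-arid scene with an injected wet-to-dry profile, shared by
# the recovery and power tests
signal_scene <- function() fixture("signal_scene", {
  generate_scene(scene_config(
    grid_shape = c(24L, 24L), n_fire_cells = 500L,
    signal_profile = c(0.5, 0.3, 0, -0.3, -0.5, -0.6),
    humid_fraction = 0, rng_seed = 421L))
})

# small mixed-regime null scene for pipeline-level tests
null_scene_small <- function() fixture("null_scene_small", {
  generate_scene(scene_config(
    grid_shape = c(12L, 12L), n_fire_cells = 100L, rng_seed = 77L))
})

# z-scores recomputed by direct per-cell, per-month-of-year loops: the
# independent oracle for the climatology/anomaly path
brute_force_z <- function(field, period = NULL) {
  d <- dim(field$values)
  nt <- d[3]
  ym <- index_to_ym(seq_len(nt), field$start)
  if (is.null(period)) period <- range(ym[, "year"])
  z <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    for (m in 1:12) {
      tt <- which(index_to_moy(seq_len(nt), field$start) == m)
      ref <- tt[ym[tt, "year"] >= period[1] & ym[tt, "year"] <= period[2]]
      x <- field$values[i, j, ref]
      x <- x[!is.na(x)]
      if (length(x) < 2) next
      s <- stats::sd(x)
      if (s == 0) next
      mu <- mean(x)
      z[i, j, tt] <- (field$values[i, j, tt] - mu) / s
    }
  }
  z
}
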