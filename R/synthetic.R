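#' Configuration for a synthetic satellite scene
#'
#' Describes a self-contained synthetic scene with the statistical structure
#' the composite analysis assumes: seasonal cycles plus AR(1) interannual
#' noise in soil moisture and vegetation optical depth (VOD), daily
#' observation gaps, a burned-area field whose retained cells each carry one
#' dominant burn month, humid/arid cells whose aridity index straddles the
#' regime boundary of 2 by construction, and a heavy-tailed lognormal
#' population-density layer.
#'
#' The fire-preceding soil-moisture signal is specified in z-score space:
#' `signal_profile[k]` is added to the standardised monthly soil-moisture
#' anomaly at lag `-(L - k)` relative to each injected burn month, where
#' `L = length(signal_profile) - 1` (the last element is lag 0, the fire
#' month itself). A profile of zeros (the default `rep(0, 6)`) gives a null
#' scene with no fire-linked signal.
#'
#' @param grid_shape integer `c(n_lat, n_lon)`.
#' @param cell_size_deg cell size in degrees.
#' @param period integer `c(start_year, end_year)`, inclusive calendar years;
#'   must span at least 2 years so every month-of-year has >= 2 climatology
#'   samples.
#' @param sm_seasonal_amp amplitude of the soil-moisture seasonal cycle
#'   (volumetric fraction).
#' @param sm_noise_sd standard deviation of monthly soil-moisture anomalies
#'   (volumetric fraction).
#' @param daily_gap_prob per-day, per-cell probability that a daily
#'   observation is missing; in `[0, 1)`.
#' @param n_fire_cells number of cells given an injected dominant burn month.
#' @param signal_profile numeric vector of z-score shifts at lags
#'   `-L..0` before/at the burn month; length <= 12.
#' @param humid_fraction proportion of cells drawn as humid (aridity <= 2).
#' @param pop_lognormal_params `c(meanlog, sdlog)` of the population-density
#'   distribution (people/km^2). The default gives a 25th percentile of
#'   about 1.68 people/km^2.
#' @param temp_range range (degrees C) of cell long-term mean temperature,
#'   drawn uniformly; the lower end below 0 exercises the cold-cell filter.
#' @param rng_seed integer seed; fixing it makes the scene bit-reproducible.
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(grid_shape = c(20L, 20L),
                         cell_size_deg = 0.25,
                         period = c(2001L, 2018L),
                         sm_seasonal_amp = 0.08,
                         sm_noise_sd = 0.04,
                         daily_gap_prob = 0.1,
                         n_fire_cells = 300L,
                         signal_profile = rep(0, 6),
                         humid_fraction = 0.5,
                         pop_lognormal_params = c(1.87, 2),
                         temp_range = c(-2, 28),
                         rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              cell_size_deg = cell_size_deg,
              period = as.integer(period),
              sm_seasonal_amp = sm_seasonal_amp,
              sm_noise_sd = sm_noise_sd,
              daily_gap_prob = daily_gap_prob,
              n_fire_cells = as.integer(n_fire_cells),
              signal_profile = as.numeric(signal_profile),
              humid_fraction = humid_fraction,
              pop_lognormal_params = as.numeric(pop_lognormal_params),
              temp_range = as.numeric(temp_range),
              rng_seed = as.integer(rng_seed))
  errs <- character()
  if (length(cfg$grid_shape) != 2 || any(cfg$grid_shape < 1))
    errs <- c(errs, "grid_shape must be two positive counts")
  if (diff(cfg$period) + 1L < 2L)
    errs <- c(errs, "period must span at least 2 years")
  if (cfg$daily_gap_prob < 0 || cfg$daily_gap_prob >= 1)
    errs <- c(errs, "daily_gap_prob must be in [0, 1)")
  if (length(cfg$signal_profile) > 12)
    errs <- c(errs, "signal_profile length must be <= 12")
  if (cfg$n_fire_cells > prod(cfg$grid_shape))
    errs <- c(errs, sprintf("n_fire_cells (%d) exceeds grid size (%d)",
                            cfg$n_fire_cells, prod(cfg$grid_shape)))
  n_months <- (diff(cfg$period) + 1L) * 12L
  if (length(cfg$signal_profile) + 1L > n_months)
    errs <- c(errs, "signal injection window extends outside the period")
  if (cfg$humid_fraction < 0 || cfg$humid_fraction > 1)
    errs <- c(errs, "humid_fraction must be in [0, 1]")
  if (length(errs))
    stop("invalid scene_config:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- "scene_config"
  cfg
}

# latent heat of vaporisation used throughout (J/kg)
LAMBDA_VAPORISATION <- 2.45e6

# equivalent evaporation depth (mm/day) of a net-radiation flux (W/m^2)
rn_to_equiv_evap <- function(rn_wm2) rn_wm2 * 86400 / LAMBDA_VAPORISATION

#' Generate a synthetic scene
#'
#' Produces every gridded input the pipeline consumes, plus a truth record
#' of the injected burn events, the injected z-profile, and the per-cell
#' humid/arid regime labels.
#'
#' Construction, per cell: monthly soil moisture is
#' `baseline + seasonal(moy) + sm_noise_sd * z(t)`, where `z` is a
#' standardised AR(1) series (lag-1 coefficient 0.5); daily values add
#' white observation noise around the month's value and are clipped to
#' `[0, 1]`; daily gaps are independent Bernoulli draws. VOD follows the
#' same recipe on a different scale. For each designated fire cell one
#' admissible month gets a burned-area fraction drawn from a Pareto
#' (heavy-tailed) law, strictly exceeding every other month of that cell,
#' and `signal_profile` is added to the soil-moisture z-series over the
#' lags ending at that month. Humid cells receive period-mean precipitation
#' exceeding their net radiation expressed as equivalent evaporation, arid
#' cells the reverse, so the computed aridity index straddles 2 by
#' construction.
#'
#' @param config a [scene_config].
#' @return a list of class `fc_scene` with elements `sm_daily`, `vod_daily`
#'   ([daily_field]), `temperature`, `precipitation`, `net_radiation`,
#'   `burned_area`, `observed_fraction` ([monthly_field]), `population`,
#'   `land_area` ([static_field]), `truth` (a list: `events` data frame with
#'   one row per injected event, `profile`, `lags`, `regime` label matrix),
#'   and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$rng_seed)
  nlat <- config$grid_shape[1]; nlon <- config$grid_shape[2]
  ncell <- nlat * nlon
  y0 <- config$period[1]; y1 <- config$period[2]
  nyears <- y1 - y0 + 1L
  nm <- nyears * 12L
  cs <- config$cell_size_deg
  # put the scene in the subtropics; absolute location is immaterial
  grid <- fc_grid(lat = 20 + cs * (seq_len(nlat) - 0.5),
                  lon = -100 + cs * (seq_len(nlon) - 0.5),
                  cell_size = cs)
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y1)), by = "day")
  nd <- length(dates)
  month_of_date <- ym_to_index(as.integer(format(dates, "%Y")),
                               as.integer(format(dates, "%m")),
                               c(y0, 1L))
  moy <- index_to_moy(seq_len(nm), c(y0, 1L))

  # --- fire cells, event months, regimes -----------------------------------
  L <- length(config$signal_profile) - 1L   # lags -L..0
  fire_cells <- sort(sample.int(ncell, config$n_fire_cells))
  # event month at least L months after start and >= 1 month before the end
  event_month <- sample(seq.int(L + 1L, nm - 1L),
                        config$n_fire_cells, replace = TRUE)
  n_humid <- round(config$humid_fraction * ncell)
  regime <- rep("arid", ncell)
  if (n_humid > 0) regime[sample.int(ncell, n_humid)] <- "humid"

  # --- standardised AR(1) monthly anomaly series (cells x months) ----------
  ar1_z <- function() {
    phi <- 0.5
    innov <- matrix(stats::rnorm(ncell * nm, sd = sqrt(1 - phi^2)), ncell, nm)
    z <- matrix(0, ncell, nm)
    z[, 1] <- stats::rnorm(ncell)
    for (t in 2:nm) z[, t] <- phi * z[, t - 1] + innov[, t]
    z
  }

  monthly_from_parts <- function(base, seas_amp_cell, phase, noise_sd, z) {
    # matrix + vector recycles down the cell dimension
    seas <- seas_amp_cell *
      sin(2 * pi * (matrix(moy, ncell, nm, byrow = TRUE) + phase) / 12)
    base + seas + noise_sd * z
  }

  expand_daily <- function(monthly_cells, daily_noise_sd, clip = NULL) {
    vals <- monthly_cells[, month_of_date, drop = FALSE] +
      matrix(stats::rnorm(ncell * nd, sd = daily_noise_sd), ncell, nd)
    if (!is.null(clip)) vals <- pmin(pmax(vals, clip[1]), clip[2])
    gaps <- matrix(stats::runif(ncell * nd) < config$daily_gap_prob, ncell, nd)
    vals[gaps] <- NA_real_
    array(vals, dim = c(nlat, nlon, nd))
  }

  # soil moisture
  sm_z <- ar1_z()
  if (length(config$signal_profile)) {
    for (k in 0:L) {
      t_inj <- event_month - (L - k)
      sm_z[cbind(fire_cells, t_inj)] <-
        sm_z[cbind(fire_cells, t_inj)] + config$signal_profile[k + 1L]
    }
  }
  sm_base <- stats::runif(ncell, 0.15, 0.35)
  sm_phase <- stats::runif(ncell, 0, 12)
  sm_monthly <- monthly_from_parts(sm_base, rep(config$sm_seasonal_amp, ncell),
                                   sm_phase, config$sm_noise_sd, sm_z)
  sm_daily <- daily_field(expand_daily(sm_monthly, 0.01, clip = c(0, 1)),
                          grid, dates, units = "m3 m-3")

  # vegetation optical depth (biomass proxy)
  vod_z <- ar1_z()
  vod_base <- stats::runif(ncell, 0.4, 0.9)
  vod_phase <- stats::runif(ncell, 0, 12)
  vod_monthly <- monthly_from_parts(vod_base, rep(0.1, ncell), vod_phase,
                                    0.05, vod_z)
  vod_daily <- daily_field(expand_daily(vod_monthly, 0.01, clip = c(0, 3)),
                           grid, dates, units = "dimensionless")

  # temperature (monthly, deg C)
  t_base <- stats::runif(ncell, config$temp_range[1], config$temp_range[2])
  t_amp <- stats::runif(ncell, 2, 8)
  t_phase <- stats::runif(ncell, 0, 12)
  t_monthly <- monthly_from_parts(t_base, t_amp, t_phase, 1, ar1_z())
  temperature <- monthly_field(array(t_monthly, c(nlat, nlon, nm)),
                               grid, c(y0, 1L), units = "degC")

  # precipitation and net radiation, tied to the drawn regime so the
  # aridity index (period-mean equivalent evaporation / period-mean
  # precipitation) lands on the intended side of 2
  p_mean <- stats::runif(ncell, 1, 5)                       # mm/day
  aridity_target <- ifelse(regime == "humid",
                           stats::runif(ncell, 0.6, 1.8),
                           stats::runif(ncell, 2.5, 6))
  e_mean <- aridity_target * p_mean                         # mm/day equiv evap
  rn_mean <- e_mean * LAMBDA_VAPORISATION / 86400           # W/m^2
  p_monthly <- p_mean * matrix(stats::rgamma(ncell * nm, shape = 16, rate = 16),
                               ncell, nm)
  rn_monthly <- rn_mean * (1 + 0.05 * matrix(stats::rnorm(ncell * nm), ncell, nm))
  precipitation <- monthly_field(array(p_monthly, c(nlat, nlon, nm)),
                                 grid, c(y0, 1L), units = "mm day-1")
  net_radiation <- monthly_field(array(rn_monthly, c(nlat, nlon, nm)),
                                 grid, c(y0, 1L), units = "W m-2")

  # burned area (km^2) + observed-area fraction
  lat_mat <- matrix(grid$lat, nlat, nlon)
  km_per_deg <- 111.32
  land_km2 <- (km_per_deg * cs)^2 * cos(pmin(abs(lat_mat), 89) * pi / 180)
  land_area <- static_field(land_km2, grid, units = "km2")
  ba <- matrix(0, ncell, nm)
  # Pareto(shape 1.5) burned fraction, capped below 0.95 of the cell
  u <- stats::runif(config$n_fire_cells)
  event_frac <- pmin(0.02 * u^(-1 / 1.5), 0.95)
  land_vec <- as.vector(land_km2)
  ba[cbind(fire_cells, event_month)] <- event_frac * land_vec[fire_cells]
  # background burning strictly below the event in fire cells only
  bg_scale <- stats::runif(config$n_fire_cells, 0, 0.3)
  for (i in seq_along(fire_cells)) {
    cell <- fire_cells[i]
    months_bg <- setdiff(seq_len(nm), event_month[i])
    on <- stats::runif(length(months_bg)) < 0.15
    ba[cell, months_bg[on]] <- ba[cell, event_month[i]] * bg_scale[i] *
      stats::runif(sum(on))
  }
  burned_area <- monthly_field(array(ba, c(nlat, nlon, nm)),
                               grid, c(y0, 1L), units = "km2")
  obs_frac <- 1 - config$daily_gap_prob *
    matrix(stats::runif(ncell * nm), ncell, nm)
  obs_frac[cbind(fire_cells, event_month)] <- 1   # events always observable
  observed_fraction <- monthly_field(array(obs_frac, c(nlat, nlon, nm)),
                                     grid, c(y0, 1L), units = "fraction")

  population <- static_field(
    matrix(stats::rlnorm(ncell, config$pop_lognormal_params[1],
                         config$pop_lognormal_params[2]), nlat, nlon),
    grid, units = "people km-2")

  ev_ym <- index_to_ym(event_month, c(y0, 1L))
  if (config$n_fire_cells == 1L) ev_ym <- matrix(ev_ym, 1L, 2L,
                                                 dimnames = list(NULL, c("year", "month")))
  truth <- list(
    events = data.frame(
      cell = fire_cells,
      lat_idx = (fire_cells - 1L) %% nlat + 1L,
      lon_idx = (fire_cells - 1L) %/% nlat + 1L,
      event_index = event_month,
      event_year = ev_ym[, "year"],
      event_month = ev_ym[, "month"],
      ba_fraction = event_frac),
    profile = config$signal_profile,
    lags = seq.int(-L, 0L),
    regime = matrix(regime, nlat, nlon))
  stopifnot(!anyDuplicated(truth$events$cell))

  structure(list(sm_daily = sm_daily, vod_daily = vod_daily,
                 temperature = temperature, precipitation = precipitation,
                 net_radiation = net_radiation, burned_area = burned_area,
                 observed_fraction = observed_fraction,
                 population = population, land_area = land_area,
                 truth = truth, config = config),
            class = "fc_scene")
}

#' @export
print.fc_scene <- function(x, ...) {
  cat(sprintf("<fc_scene> %d x %d grid, %d-%d, %d injected fire cells\n",
              x$config$grid_shape[1], x$config$grid_shape[2],
              x$config$period[1], x$config$period[2],
              nrow(x$truth$events)))
  invisible(x)
}
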