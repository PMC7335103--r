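#' Default pipeline configuration
#'
#' All thresholds of the analysis with their standard values: 80%
#' observed-area fraction, 15-day monthly minimum, 0 degrees C cold-cell
#' cut, 25th-percentile population cut, 25-cell minimum box size, humid/
#' arid split at aridity 2, 1,000 resampling repetitions with a (5, 95)
#' percentile band, headline lags -5 and -1, and evolution lags -12..+6.
#'
#' @return a named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(min_obs_fraction = 0.8,
       min_days = 15L,
       temp_min = 0,
       pop_percentile = 25,
       min_box_size = 25L,
       aridity_split = 2,
       n_boot = 1000L,
       band = c(5, 95),
       headline_lags = c(-5L, -1L),
       evolution_lags = -12:6,
       sm_window = c(-5L, 1L),
       temp_edges = seq(0, 30, by = 5),
       aridity_edges = c(0.5, 1, 2, 4, 8),
       rng_seed = 1L,
       out_dir = NULL)
}

#' Validate and normalise a pipeline configuration
#'
#' Fills unset keys with the defaults of [default_pipeline_config] and
#' checks all ranges, reporting every violation at once rather than
#' stopping at the first.
#'
#' @param config named list of overrides (possibly empty).
#' @return the normalised configuration, invisibly carrying no partial
#'   fixes; stops with the full violation list if any check fails.
#' @export
validate_config <- function(config = list()) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  cfg <- utils::modifyList(def, config[setdiff(names(config), unknown)])
  errs <- character()
  if (length(unknown))
    errs <- c(errs, paste("unknown config keys:",
                          paste(unknown, collapse = ", ")))
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(cfg$min_obs_fraction >= 0 && cfg$min_obs_fraction <= 1,
      "min_obs_fraction must be in [0, 1]")
  chk(cfg$min_days >= 1 && cfg$min_days <= 31, "min_days must be in 1..31")
  chk(cfg$pop_percentile >= 0 && cfg$pop_percentile <= 100,
      "pop_percentile must be in [0, 100]")
  chk(length(cfg$band) == 2 && cfg$band[1] < cfg$band[2],
      "percentiles not ordered")
  chk(all(cfg$band >= 0 & cfg$band <= 100), "band percentiles out of [0, 100]")
  chk(!is.unsorted(cfg$headline_lags, strictly = TRUE), "headline_lags not sorted")
  chk(!is.unsorted(cfg$evolution_lags, strictly = TRUE), "evolution_lags not sorted")
  chk(cfg$n_boot >= 1, "n_boot must be positive")
  chk(cfg$min_box_size >= 1, "min_box_size must be positive")
  chk(cfg$aridity_split > 0, "aridity_split must be positive")
  chk(length(cfg$sm_window) == 2 && cfg$sm_window[1] <= cfg$sm_window[2],
      "sm_window must be an ordered pair")
  chk(cfg$aridity_split %in% cfg$aridity_edges,
      "aridity_split must be one of aridity_edges")
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Run the full composite analysis
#'
#' Sequences the stages end-to-end on a scene: daily-to-monthly
#' aggregation, z-score anomalies of soil moisture, temperature and the
#' biomass proxy, per-cell largest-burn event sampling with the filter
#' cascade, climate-box assignment, composite medians (per-box at the
#' headline lags; humid/arid regime evolutions for all three variables),
#' resampling null bands and significance flags, and a run report.
#' Deterministic under a fixed `rng_seed`.
#'
#' @param scene an `fc_scene` from [generate_scene], an `fc_scene_files`
#'   from [read_scene], or any list providing the same named gridded
#'   elements.
#' @param config pipeline overrides; see [default_pipeline_config].
#' @return a list of class `fc_result`: `events` (filtered), `boxes`,
#'   `box_table` (per-box medians at the headline lags with band bounds
#'   and significance flags), `evolution` (per-regime, per-variable
#'   composite series with band bounds), `aridity`, `regime` labels,
#'   `report`, and `config`. If `config$out_dir` is set, tab-separated
#'   tables and the report are also written there.
#' @export
run_pipeline <- function(scene, config = list()) {
  cfg <- validate_config(config)
  needed <- c("sm_daily", "vod_daily", "temperature", "precipitation",
              "net_radiation", "burned_area", "observed_fraction",
              "population", "land_area")
  miss <- needed[!vapply(needed, function(v) !is.null(scene[[v]]), logical(1))]
  if (length(miss))
    stop("input stage: missing scene variables: ", paste(miss, collapse = ", "))
  t_start <- Sys.time()

  # --- preprocess ----------------------------------------------------------
  sm_monthly <- daily_to_monthly(scene$sm_daily, cfg$min_days)
  vod_monthly <- daily_to_monthly(scene$vod_daily, cfg$min_days)
  grid <- scene$burned_area$grid
  if (!grids_identical(sm_monthly$grid, grid))
    stop("preprocess stage: soil-moisture grid does not match burned-area grid")
  sm_anom <- normalize_anomaly(sm_monthly, monthly_climatology(sm_monthly))
  vod_anom <- normalize_anomaly(vod_monthly, monthly_climatology(vod_monthly))
  temp_anom <- normalize_anomaly(scene$temperature,
                                 monthly_climatology(scene$temperature))
  temp_mean <- longterm_mean(scene$temperature)
  aridity <- compute_aridity(scene$net_radiation, scene$precipitation)
  regime <- aridity_regime(aridity, cfg$aridity_split)

  # --- event sampling ------------------------------------------------------
  candidates <- select_largest_events(scene$burned_area,
                                      scene$observed_fraction,
                                      scene$land_area,
                                      cfg$min_obs_fraction)
  if (nrow(candidates) == 0L)
    stop("event stage: no candidate events (all burned areas zero or unobserved)")
  events <- filter_events(candidates, sm_anom, temp_mean, scene$population,
                          window = cfg$sm_window, temp_min = cfg$temp_min,
                          pop_percentile = cfg$pop_percentile)
  if (nrow(events) == 0L)
    stop("filter stage: empty event set after the filter cascade")

  # --- climate boxes and composites ---------------------------------------
  boxes <- assign_boxes(events, temp_mean, aridity,
                        temp_edges = cfg$temp_edges,
                        aridity_edges = cfg$aridity_edges,
                        min_box_size = cfg$min_box_size)
  lag_sm_head <- event_lag_matrix(sm_anom, events, cfg$headline_lags)
  membership <- attr(boxes, "membership")
  retained <- which(!boxes$discarded)
  box_groups <- lapply(retained, function(b) which(membership == b))
  # sprintf keeps zero length for zero retained boxes (paste0 would not)
  names(box_groups) <- sprintf("box%d", boxes$box[retained])

  box_table <- do.call(rbind, lapply(cfg$headline_lags, function(l)
    box_composites_at_lag(lag_sm_head, boxes, l)))

  ev_regime <- regime[cbind(events$lat_idx, events$lon_idx)]
  regime_groups <- list(humid = which(ev_regime == "humid"),
                        arid = which(ev_regime == "arid"))
  regime_groups <- regime_groups[vapply(regime_groups, length, 1L) > 0]

  lag_mats <- list(soil_moisture = event_lag_matrix(sm_anom, events,
                                                    cfg$evolution_lags),
                   temperature = event_lag_matrix(temp_anom, events,
                                                  cfg$evolution_lags),
                   biomass = event_lag_matrix(vod_anom, events,
                                              cfg$evolution_lags))
  evolution <- list()
  for (v in names(lag_mats)) for (r in names(regime_groups)) {
    cs <- composite_median(lag_mats[[v]], regime_groups[[r]])
    cs$variable <- v
    cs$regime <- r
    evolution[[paste(v, r, sep = ".")]] <- cs
  }

  # --- significance --------------------------------------------------------
  if (length(box_groups)) {
    band_boxes <- null_band(sm_anom, events, box_groups, cfg$headline_lags,
                            n_boot = cfg$n_boot, percentile_pair = cfg$band,
                            rng_seed = cfg$rng_seed)
    observed <- matrix(NA_real_, length(box_groups),
                       length(cfg$headline_lags))
    for (g in seq_along(box_groups)) for (l in seq_along(cfg$headline_lags))
      observed[g, l] <- box_table$median[
        box_table$box == boxes$box[retained[g]] &
          box_table$lag == cfg$headline_lags[l]]
    flags <- flag_significant(observed, band_boxes)
    idx <- cbind(match(paste0("box", box_table$box), names(box_groups)),
                 match(box_table$lag, cfg$headline_lags))
    box_table$lower <- band_boxes$lower[idx]
    box_table$upper <- band_boxes$upper[idx]
    box_table$significant <- flags[idx]
  } else {
    band_boxes <- NULL
  }
  band_regime <- NULL
  if (length(regime_groups)) {
    band_regime <- null_band(sm_anom, events, regime_groups,
                             cfg$evolution_lags, n_boot = cfg$n_boot,
                             percentile_pair = cfg$band,
                             rng_seed = cfg$rng_seed + 1L)
    for (r in names(regime_groups)) {
      key <- paste("soil_moisture", r, sep = ".")
      ri <- match(r, names(regime_groups))
      evolution[[key]]$lower <- band_regime$lower[ri, ]
      evolution[[key]]$upper <- band_regime$upper[ri, ]
      evolution[[key]]$significant <- as.vector(flag_significant(
        matrix(evolution[[key]]$median, 1), sub_band(band_regime, ri)))
    }
  }

  report <- attr(events, "report")
  report <- rbind(report,
                  data.frame(stage = c("boxes_retained", "boxes_discarded",
                                       "events_humid", "events_arid"),
                             count = c(sum(!boxes$discarded),
                                       sum(boxes$discarded),
                                       sum(ev_regime == "humid"),
                                       sum(ev_regime == "arid"))))
  result <- structure(
    list(events = events, boxes = boxes, box_table = box_table,
         evolution = evolution, aridity = aridity, regime = regime,
         band_boxes = band_boxes, band_regime = band_regime,
         anomalies = list(soil_moisture = sm_anom, temperature = temp_anom,
                          biomass = vod_anom),
         temperature_mean = temp_mean,
         report = report, config = cfg,
         wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "fc_result")
  if (!is.null(cfg$out_dir)) write_result(result, cfg$out_dir)
  result
}

# single-row view of a null band (for flagging one group's evolution)
sub_band <- function(band, row) {
  structure(list(lower = band$lower[row, , drop = FALSE],
                 upper = band$upper[row, , drop = FALSE],
                 groups = band$groups[row], lags = band$lags,
                 n_boot = band$n_boot,
                 percentile_pair = band$percentile_pair),
            class = "null_band")
}

#' Write pipeline result tables
#'
#' Tab-separated tables (box composites, regime evolutions, filtered
#' events) plus a plain-text run report with the stage counts.
#'
#' @param result an `fc_result`.
#' @param directory output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_result <- function(result, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(
    box_table = file.path(directory, "box_composites.tsv"),
    evolution = file.path(directory, "regime_evolution.tsv"),
    events = file.path(directory, "events.tsv"),
    report = file.path(directory, "run_report.txt"))
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(result$box_table, paths["box_table"])
  evol <- do.call(rbind, lapply(result$evolution, function(e) {
    e[setdiff(c("variable", "regime", "lag", "median", "q25", "q75", "n",
                "lower", "upper", "significant"), names(e))] <- NA
    e[, c("variable", "regime", "lag", "median", "q25", "q75", "n",
          "lower", "upper", "significant")]
  }))
  wt(evol, paths["evolution"])
  wt(as.data.frame(result$events), paths["events"])
  con <- file(paths["report"], "w")
  writeLines(c(sprintf("firecomposite run report (%s)",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("wall time: %.1f s", result$wall_time_s),
               "", "stage counts:"), con)
  utils::write.table(result$report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(paths)
}

#' @export
print.fc_result <- function(x, ...) {
  cat("<fc_result>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
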