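#' Write a synthetic scene to disk
#'
#' Writes one NetCDF file per gridded variable (CF-style `lat`/`lon`/`time`
#' coordinates, `_FillValue` attribute; `time` in days since 1970-01-01 for
#' daily fields and months since the record start for monthly fields) and
#' the truth record as a tab-separated table. Requires the `ncdf4` package.
#'
#' @param scene an `fc_scene` from [generate_scene].
#' @param directory output directory (created if absent).
#' @return invisibly, a manifest data frame with columns `name`, `file`,
#'   `kind`.
#' @export
write_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "fc_scene"))
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("write_scene requires the 'ncdf4' package")
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, 2) != 0)
    stop("directory is not writable: ", directory)
  fill <- -9999.0

  vars <- c("sm_daily", "vod_daily", "temperature", "precipitation",
            "net_radiation", "burned_area", "observed_fraction",
            "population", "land_area")
  manifest <- data.frame(name = character(), file = character(),
                         kind = character())
  for (v in vars) {
    fld <- scene[[v]]
    path <- file.path(directory, paste0(v, ".nc"))
    dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", fld$grid$lat)
    dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", fld$grid$lon)
    if (inherits(fld, "daily_field")) {
      dim_t <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                                as.numeric(fld$dates), unlim = TRUE)
      kind <- "daily"
    } else if (inherits(fld, "monthly_field")) {
      nt <- n_times(fld)
      dim_t <- ncdf4::ncdim_def(
        "time",
        sprintf("months since %d-%02d-01", fld$start[1], fld$start[2]),
        seq_len(nt) - 1, unlim = TRUE)
      kind <- "monthly"
    } else {
      dim_t <- NULL
      kind <- "static"
    }
    dims <- if (is.null(dim_t)) list(dim_lat, dim_lon)
            else list(dim_lat, dim_lon, dim_t)
    nv <- ncdf4::ncvar_def(v, fld$units, dims, missval = fill, prec = "double")
    nc <- ncdf4::nc_create(path, nv)
    vals <- fld$values
    vals[is.na(vals)] <- fill
    ncdf4::ncvar_put(nc, nv, vals)
    ncdf4::ncatt_put(nc, 0, "cell_size_deg", fld$grid$cell_size)
    ncdf4::nc_close(nc)
    manifest <- rbind(manifest,
                      data.frame(name = v, file = path, kind = kind))
  }
  truth_path <- file.path(directory, "truth_events.tsv")
  utils::write.table(scene$truth$events, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  profile_path <- file.path(directory, "truth_profile.tsv")
  utils::write.table(
    data.frame(lag = scene$truth$lags, z_shift = scene$truth$profile),
    profile_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- rbind(manifest,
                    data.frame(name = c("truth_events", "truth_profile"),
                               file = c(truth_path, profile_path),
                               kind = "truth"))
  invisible(manifest)
}

#' Read back one scene variable written by [write_scene]
#'
#' @param path NetCDF file path.
#' @return a [daily_field], [monthly_field] or [static_field] depending on
#'   the stored time axis.
#' @export
read_scene_var <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("read_scene_var requires the 'ncdf4' package")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vname <- names(nc$var)[1]
  vals <- ncdf4::ncvar_get(nc, vname, collapse_degen = FALSE)
  units <- nc$var[[vname]]$units
  lat <- nc$dim$lat$vals
  lon <- nc$dim$lon$vals
  cs <- ncdf4::ncatt_get(nc, 0, "cell_size_deg")$value
  grid <- fc_grid(lat, lon, cs)
  if (is.null(nc$dim$time))
    return(static_field(matrix(vals, length(lat), length(lon)), grid, units))
  tunits <- nc$dim$time$units
  tvals <- nc$dim$time$vals
  vals <- array(vals, dim = c(length(lat), length(lon), length(tvals)))
  if (grepl("^days since 1970-01-01", tunits)) {
    daily_field(vals, grid, as.Date(tvals, origin = "1970-01-01"), units)
  } else if (grepl("^months since", tunits)) {
    start <- as.integer(strsplit(sub("^months since ", "", tunits),
                                 "-")[[1]][1:2])
    monthly_field(vals, grid, start, units)
  } else stop("unrecognised time units: ", tunits)
}

#' Read a whole scene directory written by [write_scene]
#'
#' @param directory directory produced by [write_scene].
#' @return a list with the same gridded elements as an `fc_scene` plus the
#'   truth tables (no config; class `fc_scene_files`).
#' @export
read_scene <- function(directory) {
  vars <- c("sm_daily", "vod_daily", "temperature", "precipitation",
            "net_radiation", "burned_area", "observed_fraction",
            "population", "land_area")
  out <- lapply(vars, function(v)
    read_scene_var(file.path(directory, paste0(v, ".nc"))))
  names(out) <- vars
  ev <- file.path(directory, "truth_events.tsv")
  pr <- file.path(directory, "truth_profile.tsv")
  if (file.exists(ev)) {
    prof <- utils::read.delim(pr)
    out$truth <- list(events = utils::read.delim(ev),
                      profile = prof$z_shift, lags = prof$lag)
  }
  structure(out, class = "fc_scene_files")
}
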