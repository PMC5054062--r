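#' Read an observation table
#'
#' Delimited text with header
#' `station_id,lat,lon,land_use,pollutant,time_utc,value` (QC output adds
#' `qc_flags,accepted`).  Malformed rows (missing or non-numeric `value`,
#' bad coordinates) are rejected with their line numbers.
#'
#' @param path File path.
#' @return List with `obs` (data frame) and `stations` (a [station_set]
#'   of the unique sites in the file).
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("station_id", "lat", "lon", "land_use", "pollutant",
           "time_utc", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("observation file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val))
  if (length(bad))
    stop("non-numeric or missing 'value' at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  df$value <- val
  st <- unique(df[c("station_id", "lat", "lon", "land_use")])
  names(st)[1] <- "id"
  list(obs = df, stations = station_set(st))
}

#' @rdname read_observations
#' @param obs Observation data frame (column names as above).
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a grid field as a CSV raster
#'
#' Self-describing plain-text raster: `#`-prefixed header lines carry the
#' metadata (`pollutant`, `units`, `valid_time`, `dx_km`, `lats`, `lons`),
#' followed by the value matrix (rows = latitudes south to north, columns
#' = longitudes west to east).  Round-trips a [grid_field] value-exactly.
#'
#' @param path File path.
#' @return `read_grid`: a [grid_field].
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) stop("grid file ", path, " missing header '", key, "'")
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  pollutant <- get("pollutant")
  units <- get("units")
  known <- c("ppbv", "ug/m3", "1")
  if (!units %in% known)
    stop("grid file ", path, ": unknown units '", units, "'")
  valid_time <- as.numeric(get("valid_time"))
  dx_km <- as.numeric(get("dx_km"))
  lats <- as.numeric(strsplit(get("lats"), ",")[[1]])
  lons <- as.numeric(strsplit(get("lons"), ",")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  vals <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(l, ",")[[1]])))
  grid_field(lats, lons, vals, pollutant, valid_time = valid_time,
             dx_km = dx_km, units = units)
}

#' @rdname read_grid
#' @param field A [grid_field].
#' @export
write_grid <- function(field, path) {
  stopifnot(inherits(field, "grid_field"))
  hdr <- c(paste0("# pollutant: ", field$pollutant),
           paste0("# units: ", field$units),
           paste0("# valid_time: ", as.numeric(field$valid_time)),
           paste0("# dx_km: ", field$dx_km),
           paste0("# lats: ", paste(format(field$lats, digits = 15),
                                    collapse = ",")),
           paste0("# lons: ", paste(format(field$lons, digits = 15),
                                    collapse = ",")))
  body <- apply(field$values, 1, function(r)
    paste(format(r, digits = 15, trim = TRUE), collapse = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write error statistics as YAML
#'
#' @param path File path.
#' @return `read_error_stats`: an [error_stats].
#' @export
read_error_stats <- function(path) {
  y <- yaml::read_yaml(path)
  error_stats(pollutant = y$pollutant, sigma_b2 = y$sigma_b2,
              lc_km = y$lc_km,
              sigma_o2_by_station = unlist(y$sigma_o2_by_station),
              sigma_b2_by_station = unlist(y$sigma_b2_by_station),
              sigma_o2_by_class = unlist(y$sigma_o2_by_class),
              stratum = if (is.null(y$stratum)) "all" else y$stratum,
              source = if (is.null(y$source)) "prescribed" else y$source)
}

#' @rdname read_error_stats
#' @param stats An [error_stats].
#' @export
write_error_stats <- function(stats, path) {
  yaml::write_yaml(list(
    pollutant = stats$pollutant, stratum = stats$stratum,
    sigma_b2 = stats$sigma_b2, lc_km = stats$lc_km,
    sigma_o2_by_station = as.list(stats$sigma_o2_by_station),
    sigma_b2_by_station = as.list(stats$sigma_b2_by_station),
    sigma_o2_by_class = as.list(stats$sigma_o2_by_class),
    source = stats$source), path)
  invisible(path)
}

#' Read bias regions from YAML
#'
#' The file holds a list of regions, each with `name`, `lat`, `lon`
#' vertex vectors and optional `decay_km`/`min_stations`.
#'
#' @param path File path.
#' @return List of [bias_region]s.
#' @export
read_bias_regions <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(r)
    bias_region(r$name, unlist(r$lat), unlist(r$lon),
                decay_km = if (is.null(r$decay_km)) 100 else r$decay_km,
                min_stations = if (is.null(r$min_stations)) 5
                               else r$min_stations))
}

#' Export an analysis product as a four-panel file set
#'
#' Writes the forecast, analysis and increment rasters plus the table of
#' assimilated observations: the standard presentation of one analysis
#' (model trial field, objective analysis, increments, observations
#' used).
#'
#' @param product An `analysis_product`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the pollutant).
#' @return Invisibly, the four file paths.
#' @export
four_panel_export <- function(product, dir,
                              prefix = product$forecast$pollutant) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, "_",
                             c("forecast", "analysis", "increment"),
                             ".csvgrid"))
  write_grid(product$forecast, p[1])
  write_grid(product$analysis, p[2])
  write_grid(product$increment, p[3])
  innov <- product$innovations
  obs_tab <- data.frame(station_id = innov$stations$id,
                        lat = innov$stations$lat,
                        lon = innov$stations$lon,
                        observed = innov$y_o, forecast_at_station = innov$h_xf,
                        innovation = innov$d)
  p4 <- file.path(dir, paste0(prefix, "_observations.csv"))
  utils::write.csv(obs_tab, p4, row.names = FALSE, quote = FALSE)
  invisible(c(p, p4))
}

#' Write a validation report as a delimited table
#'
#' @param report A `validation_report` from [cross_validate].
#' @param path File path.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report$by_hour, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
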