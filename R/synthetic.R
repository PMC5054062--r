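#' Synthetic station network
#'
#' Places `n_stations` at random inside the grid's bounding box (uniform,
#' or clustered around a few random centers) and assigns land-use classes
#' by the configured mix.  Deterministic under `seed`.
#'
#' @param grid A [grid_field] (only its extent is used).
#' @param n_stations Number of stations.
#' @param land_use_mix Fractions (rural, suburban, urban), summing to 1.
#' @param clustered Place stations around `n_clusters` random centers
#'   instead of uniformly (emulates the strong density contrasts of real
#'   networks).
#' @param n_clusters Number of cluster centers in clustered mode.
#' @param seed Integer seed.
#' @return A [station_set].
#' @export
make_station_network <- function(grid, n_stations,
                                 land_use_mix = c(rural = 0.3,
                                                  suburban = 0.3,
                                                  urban = 0.4),
                                 clustered = FALSE, n_clusters = 5,
                                 seed = 1) {
  stopifnot(n_stations >= 1)
  if (abs(sum(land_use_mix) - 1) > 1e-8)
    stop("land_use_mix fractions must sum to 1")
  set.seed(seed)
  rlat <- range(grid$lats); rlon <- range(grid$lons)
  if (clustered) {
    clat <- stats::runif(n_clusters, rlat[1], rlat[2])
    clon <- stats::runif(n_clusters, rlon[1], rlon[2])
    k <- sample(n_clusters, n_stations, replace = TRUE)
    spread_lat <- diff(rlat) / 12
    spread_lon <- diff(rlon) / 12
    lat <- pmin(pmax(clat[k] + stats::rnorm(n_stations, 0, spread_lat),
                     rlat[1]), rlat[2])
    lon <- pmin(pmax(clon[k] + stats::rnorm(n_stations, 0, spread_lon),
                     rlon[1]), rlon[2])
  } else {
    lat <- stats::runif(n_stations, rlat[1], rlat[2])
    lon <- stats::runif(n_stations, rlon[1], rlon[2])
  }
  classes <- sample(c("rural", "suburban", "urban"), n_stations,
                    replace = TRUE, prob = land_use_mix)
  station_set(data.frame(id = sprintf("S%04d", seq_len(n_stations)),
                         lat = lat, lon = lon, land_use = classes,
                         stringsAsFactors = FALSE))
}

# dense Cholesky factor of an exponential covariance over points, cached
# per (coords, variance, lc) within one generator call
exp_cov_chol <- function(lat, lon, variance, lc_km) {
  d <- distance_matrix_km(lat, lon)
  C <- variance * exp(-d / lc_km)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(C + diag(1e-8 * variance, nrow(C))),
                   error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix not positive definite")
  }
  ch
}

#' Simulate a spatially correlated truth field
#'
#' Draws a Gaussian random field on the grid's cell centers with mean
#' `mean`, variance `variance` and exponential spatial covariance
#' `variance * exp(-d / lc_km)` (dense Cholesky construction: exact, for
#' grids up to a few thousand cells).
#'
#' @param grid Template [grid_field] (geometry and metadata reused).
#' @param mean Field mean.
#' @param variance Field variance (0 gives the constant field).
#' @param lc_km Spatial correlation length in km.
#' @param seed Integer seed.
#' @param n_fields Number of independent draws (default 1).
#' @return A [grid_field] (or a list of them when `n_fields > 1`).
#' @export
simulate_truth <- function(grid, mean, variance, lc_km, seed = 1,
                           n_fields = 1) {
  nlat <- length(grid$lats); nlon <- length(grid$lons)
  ncell <- nlat * nlon
  if (ncell > 5000)
    stop("grid too large for dense covariance factorization (> 5000 cells)")
  make_one <- function(z) {
    g <- grid
    g$values <- matrix(z, nlat, nlon)
    g
  }
  set.seed(seed)
  if (variance == 0) {
    draws <- matrix(mean, ncell, n_fields)
  } else {
    glat <- rep(grid$lats, times = nlon)
    glon <- rep(grid$lons, each = nlat)
    ch <- exp_cov_chol(glat, glon, variance, lc_km)
    zmat <- matrix(stats::rnorm(ncell * n_fields), ncell, n_fields)
    draws <- mean + crossprod(ch, zmat)
  }
  fields <- lapply(seq_len(n_fields), function(i) make_one(draws[, i]))
  if (n_fields == 1L) fields[[1]] else fields
}

#' Simulate a model forecast from a truth field
#'
#' Adds a spatially correlated background error of variance `sigma_b2` and
#' correlation length `lc_bg_km` to the truth, plus optional constant
#' regional offsets (a biased model inside [bias_region]s).
#'
#' @param truth Truth [grid_field] (or list of them for several hours).
#' @param sigma_b2 Background error variance.
#' @param lc_bg_km Background error correlation length in km.
#' @param bias_regions Optional list of [bias_region]s.
#' @param bias_offsets Constant offsets added to the forecast inside each
#'   region (aligned with `bias_regions`).
#' @param seed Integer seed.
#' @return Forecast [grid_field] (or list of them).
#' @export
simulate_forecast <- function(truth, sigma_b2, lc_bg_km,
                              bias_regions = NULL, bias_offsets = NULL,
                              seed = 1) {
  single <- inherits(truth, "grid_field")
  truths <- if (single) list(truth) else truth
  g <- truths[[1]]
  nlat <- length(g$lats); nlon <- length(g$lons)
  ncell <- nlat * nlon
  set.seed(seed)
  if (sigma_b2 > 0) {
    glat <- rep(g$lats, times = nlon)
    glon <- rep(g$lons, each = nlat)
    ch <- exp_cov_chol(glat, glon, sigma_b2, lc_bg_km)
    zmat <- matrix(stats::rnorm(ncell * length(truths)), ncell,
                   length(truths))
    err <- crossprod(ch, zmat)
  } else {
    err <- matrix(0, ncell, length(truths))
  }
  offset <- matrix(0, nlat, nlon)
  if (!is.null(bias_regions)) {
    glat <- rep(g$lats, times = nlon)
    glon <- rep(g$lons, each = nlat)
    for (m in seq_along(bias_regions)) {
      inside <- point_in_polygon(glat, glon, bias_regions[[m]])
      offset <- offset + matrix(inside * bias_offsets[m], nlat, nlon)
    }
  }
  out <- lapply(seq_along(truths), function(i) {
    f <- truths[[i]]
    f$values <- truths[[i]]$values + matrix(err[, i], nlat, nlon) + offset
    f
  })
  if (single) out[[1]] else out
}

#' Simulate station observations from a truth field
#'
#' Observations are the truth bilinearly interpolated to the stations plus
#' white noise whose variance follows the representativeness model for the
#' station's land-use class ([obs_error_s14]); noise is independent across
#' stations and hours.
#'
#' @param truth Truth [grid_field] (or list of them for several hours).
#' @param stations [station_set].
#' @param sigma_instr2 Instrument error variance.
#' @param seed Integer seed.
#' @param n Effective-resolution multiplier of the representativeness
#'   model (default 4).
#' @return Data frame `station_id, time, value` (time = position in the
#'   truth list, 1-based), with attribute `"sigma_o2"` giving the noise
#'   variance used per station.
#' @export
simulate_observations <- function(truth, stations, sigma_instr2, seed = 1,
                                  n = 4) {
  single <- inherits(truth, "grid_field")
  truths <- if (single) list(truth) else truth
  so2 <- obs_error_s14(sigma_instr2, truths[[1]]$dx_km, stations$land_use,
                       n = n)
  set.seed(seed)
  out <- lapply(seq_along(truths), function(h) {
    tv <- interpolate_to_stations(truths[[h]], stations)
    data.frame(station_id = stations$id, time = h,
               value = tv + stats::rnorm(nrow(stations), 0, sqrt(so2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[is.finite(out$value), , drop = FALSE]
  attr(out, "sigma_o2") <- stats::setNames(so2, stations$id)
  out
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper producing everything the analysis chain consumes
#' with known truth: a grid, a station network, hourly truth fields,
#' forecasts (truth + correlated background error + optional regional
#' bias) and noisy observations.
#'
#' @param n_lat,n_lon Grid dimensions (cell centers).
#' @param lat_range,lon_range Grid extents in degrees.
#' @param dx_km Nominal resolution metadata.
#' @param pollutant Pollutant name.
#' @param n_stations,land_use_mix,clustered Network parameters.
#' @param n_hours Number of hourly fields.
#' @param truth_mean,truth_var,truth_lc_km Truth field parameters.
#' @param sigma_b2,lc_bg_km Background error parameters.
#' @param sigma_instr2 Instrument error variance.
#' @param bias_regions,bias_offsets Optional regional model bias.
#' @param seed Integer seed controlling every draw.
#' @return List with `grid`, `stations`, `truths`, `forecasts`, `obs`,
#'   `sigma_o2` (per-station true observation error variances) and the
#'   generating parameters in `config`.
#' @export
simulate_scene <- function(n_lat = 26, n_lon = 28,
                           lat_range = c(43, 45.5),
                           lon_range = c(-76, -72.5),
                           dx_km = 10, pollutant = "O3",
                           n_stations = 100,
                           land_use_mix = c(rural = 0.3, suburban = 0.3,
                                            urban = 0.4),
                           clustered = FALSE, n_hours = 24,
                           truth_mean = 40, truth_var = 100,
                           truth_lc_km = 200,
                           sigma_b2 = 25, lc_bg_km = 60,
                           sigma_instr2 = default_sigma_instr2(pollutant),
                           bias_regions = NULL, bias_offsets = NULL,
                           seed = 1) {
  template <- grid_field(seq(lat_range[1], lat_range[2], length.out = n_lat),
                         seq(lon_range[1], lon_range[2], length.out = n_lon),
                         matrix(0, n_lat, n_lon), pollutant, dx_km = dx_km)
  stations <- make_station_network(template, n_stations, land_use_mix,
                                   clustered = clustered, seed = seed)
  truths <- simulate_truth(template, truth_mean, truth_var, truth_lc_km,
                           seed = seed + 1L, n_fields = n_hours)
  if (n_hours == 1L) truths <- list(truths)
  truths <- lapply(seq_along(truths), function(i) {
    g <- truths[[i]]; g$valid_time <- i; g
  })
  forecasts <- simulate_forecast(truths, sigma_b2, lc_bg_km,
                                 bias_regions, bias_offsets,
                                 seed = seed + 2L)
  obs <- simulate_observations(truths, stations, sigma_instr2,
                               seed = seed + 3L)
  list(grid = template, stations = stations, truths = truths,
       forecasts = forecasts, obs = obs,
       sigma_o2 = attr(obs, "sigma_o2"),
       config = list(truth_mean = truth_mean, truth_var = truth_var,
                     truth_lc_km = truth_lc_km, sigma_b2 = sigma_b2,
                     lc_bg_km = lc_bg_km, sigma_instr2 = sigma_instr2,
                     n_hours = n_hours, seed = seed))
}

#' OmP matrix of a synthetic scene
#'
#' Observation-minus-forecast values arranged hours x stations, the input
#' shape of [compute_innovation_stats].
#'
#' @param scene A scene from [simulate_scene].
#' @return Numeric matrix with station ids as column names.
#' @export
scene_omp_matrix <- function(scene) {
  ids <- scene$stations$id
  n_hours <- length(scene$forecasts)
  omp <- matrix(NA_real_, n_hours, length(ids),
                dimnames = list(NULL, ids))
  for (h in seq_len(n_hours)) {
    hxf <- interpolate_to_stations(scene$forecasts[[h]], scene$stations)
    oh <- scene$obs[scene$obs$time == h, , drop = FALSE]
    j <- match(oh$station_id, ids)
    omp[h, j] <- oh$value - hxf[j]
  }
  omp
}
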