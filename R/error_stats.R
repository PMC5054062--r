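#' Error statistics for one pollutant and stratum
#'
#' Bundles everything the analysis needs to know about uncertainty: the
#' domain-mean background error variance `sigma_b2` (concentration
#' squared), optional per-station background variances, per-station or
#' per-land-use observation error variances, and the background error
#' correlation length `lc_km`.  `lambda_ratio` is the background-to-
#' observation error variance ratio that controls the analysis gain.
#'
#' @param pollutant Pollutant name.
#' @param sigma_b2 Domain-mean background error variance (> 0).
#' @param lc_km Correlation length in km; must lie in \[5, 500\].
#' @param sigma_o2_by_station Optional named vector of observation error
#'   variances keyed by station id.
#' @param sigma_b2_by_station Optional named vector of per-station
#'   background error variances keyed by station id.
#' @param sigma_o2_by_class Optional named vector of observation error
#'   variances keyed by land-use class (`rural`, `suburban`, `urban`);
#'   used for stations without a per-station value.
#' @param stratum Label of the (UTC hour, season) stratum, or `"all"`.
#' @param source Provenance tag: `"HL86"`, `"S14"`, `"blended"` or
#'   `"prescribed"`.
#' @return Object of class `error_stats`.
#' @export
error_stats <- function(pollutant, sigma_b2, lc_km,
                        sigma_o2_by_station = NULL,
                        sigma_b2_by_station = NULL,
                        sigma_o2_by_class = NULL,
                        stratum = "all", source = "prescribed") {
  source <- match.arg(source, c("HL86", "S14", "blended", "prescribed"))
  if (!is.numeric(sigma_b2) || sigma_b2 <= 0)
    stop("'sigma_b2' must be positive")
  if (lc_km < 5 || lc_km > 500)
    stop("'lc_km' must lie in [5, 500] km")
  for (v in list(sigma_o2_by_station, sigma_b2_by_station, sigma_o2_by_class))
    if (!is.null(v) && any(v <= 0)) stop("variances must be positive")
  so_pool <- c(sigma_o2_by_station, sigma_o2_by_class)
  lambda <- if (length(so_pool)) sigma_b2 / mean(so_pool) else NA_real_
  structure(list(pollutant = pollutant, stratum = stratum,
                 sigma_b2 = sigma_b2,
                 sigma_b2_by_station = sigma_b2_by_station,
                 sigma_o2_by_station = sigma_o2_by_station,
                 sigma_o2_by_class = sigma_o2_by_class,
                 lc_km = lc_km, lambda_ratio = lambda, source = source),
            class = "error_stats")
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf(
    "<error_stats> %s [%s] sigma_b2=%.4g lc=%g km lambda=%.3g source=%s\n",
    x$pollutant, x$stratum, x$sigma_b2, x$lc_km, x$lambda_ratio, x$source))
  invisible(x)
}

# station-side background error sd: local value when known, else the
# homogeneous domain value
station_sigma_f <- function(stats, ids) {
  sf <- rep(sqrt(stats$sigma_b2), length(ids))
  if (!is.null(stats$sigma_b2_by_station)) {
    hit <- ids %in% names(stats$sigma_b2_by_station)
    sf[hit] <- sqrt(stats$sigma_b2_by_station[ids[hit]])
  }
  unname(sf)
}

station_sigma_o2 <- function(stats, ids, land_use) {
  so2 <- rep(NA_real_, length(ids))
  if (!is.null(stats$sigma_o2_by_class))
    so2 <- unname(stats$sigma_o2_by_class[land_use])
  if (!is.null(stats$sigma_o2_by_station)) {
    hit <- ids %in% names(stats$sigma_o2_by_station)
    so2[hit] <- stats$sigma_o2_by_station[ids[hit]]
  }
  if (any(is.na(so2)))
    stop("no observation error variance for station(s): ",
         paste(utils::head(ids[is.na(so2)], 5L), collapse = ", "))
  unname(so2)
}

#' Prescribed correlation lengths by pollutant
#'
#' Innovation-based correlation lengths come out too long for surface
#' pollutants, so fixed per-pollutant values in the 10-100 km range are
#' used by default: O3 60 km, PM2.5 60 km, PM10 40 km, NO2 20 km.
#'
#' @param pollutant Pollutant name.
#' @return Correlation length in km.
#' @export
default_lc_km <- function(pollutant) {
  switch(pollutant,
         O3 = 60, "PM2.5" = 60, PM10 = 40, NO2 = 20,
         stop("no default correlation length for ", pollutant))
}

#' Default instrument error variances
#'
#' O3: 5 ppbv standard deviation; PM2.5: 2 ug/m3; NO2 and PM10: 7.5% of a
#' typical concentration (midpoint of the 5-10% relative instrument error
#' range).
#'
#' @param pollutant Pollutant name.
#' @param typical_conc Typical concentration used for the relative-error
#'   pollutants (default 30).
#' @return Instrument error variance (concentration squared).
#' @export
default_sigma_instr2 <- function(pollutant, typical_conc = 30) {
  switch(pollutant,
         O3 = 25, "PM2.5" = 4,
         NO2 = (0.075 * typical_conc)^2,
         PM10 = (0.075 * typical_conc)^2,
         stop("no default instrument error for ", pollutant))
}

#' Per-station innovation statistics
#'
#' First step of the innovation-based (variogram) estimation: compute the
#' observation-minus-prediction (OmP) time series per station over a
#' stratum and its mean and variance.  Stations with fewer paired hours
#' than `min_hours` are excluded.
#'
#' @param omp_matrix Numeric matrix of OmP values, hours in rows, stations
#'   in columns (column names = station ids); `NA` for missing pairs.
#' @param min_hours Minimum number of paired hours per station (default 30).
#' @return List with `omp` (the filtered matrix), `mean_omp`, `var_omp`
#'   (named per-station vectors) and `var_omp_zero` (the pooled mean of the
#'   per-station variances, the variogram's zero-distance value).
#' @export
compute_innovation_stats <- function(omp_matrix, min_hours = 30) {
  omp_matrix <- as.matrix(omp_matrix)
  if (!length(omp_matrix) || all(is.na(omp_matrix)))
    stop("empty observation/forecast pairing")
  n_ok <- colSums(!is.na(omp_matrix))
  keep <- n_ok >= min_hours
  if (!any(keep)) stop("no station has >= ", min_hours, " paired hours")
  omp <- omp_matrix[, keep, drop = FALSE]
  mean_omp <- colMeans(omp, na.rm = TRUE)
  var_omp <- apply(omp, 2, stats::var, na.rm = TRUE)
  list(omp = omp, mean_omp = mean_omp, var_omp = var_omp,
       var_omp_zero = mean(var_omp))
}

#' Bin station-pair OmP covariances by separation distance
#'
#' Second step of the variogram method: every pair of stations contributes
#' the covariance of their OmP time series at their separation distance.
#' Pair covariances are averaged within distance bins; the first bin
#' excludes zero distance (the origin carries the observation-error nugget
#' and is excluded from the fit).
#'
#' @param omp Matrix of OmP values (hours x stations) as returned in
#'   `compute_innovation_stats()$omp`.
#' @param stations [station_set] containing at least the stations in
#'   `colnames(omp)`.
#' @param bin_width_km Bin width (default 20 km).
#' @param max_km Maximum separation considered (default 500 km).
#' @param min_pairs Minimum station pairs for a bin to be usable
#'   (default 10).
#' @return Object of class `variogram_estimate` with `bin_centers`,
#'   `bin_covariances`, `bin_pair_counts`, `var_omp_zero`, and `fit_ok`
#'   (FALSE with a `reason` until [fit_foar] succeeds).
#' @export
bin_pair_covariances <- function(omp, stations, bin_width_km = 20,
                                 max_km = 500, min_pairs = 10) {
  ids <- colnames(omp)
  st <- stations[match(ids, stations$id), , drop = FALSE]
  if (anyNA(st$id)) stop("stations missing from station table")
  m <- ncol(omp)
  if (m < 2L) stop("need at least 2 stations with valid OmP series")
  cmat <- stats::cov(omp, use = "pairwise.complete.obs")
  dmat <- distance_matrix_km(st$lat, st$lon)
  iu <- upper.tri(dmat)
  d <- dmat[iu]; cv <- cmat[iu]
  ok <- is.finite(cv) & d > 0 & d <= max_km
  d <- d[ok]; cv <- cv[ok]
  breaks <- seq(0, max_km, by = bin_width_km)
  idx <- cut(d, breaks, labels = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  sums <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(cv[idx == b]), numeric(1))
  used <- counts >= min_pairs
  est <- structure(list(
    bin_centers = (breaks[-length(breaks)] + breaks[-1]) / 2,
    bin_covariances = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    bin_pair_counts = counts,
    bins_used = used,
    var_omp_zero = mean(apply(omp, 2, stats::var, na.rm = TRUE)),
    fitted_sill = NA_real_, fitted_lc = NA_real_, nugget = NA_real_,
    fit_ok = FALSE, reason = "not fitted"),
    class = "variogram_estimate")
  if (!any(used)) est$reason <- "insufficient pairs"
  est
}

#' Fit the exponential (first-order autoregressive) covariance model
#'
#' Third step of the variogram method: weighted nonlinear least squares of
#' `c(d) = sill * exp(-d / lc)` over the populated distance bins (weights =
#' pair counts, origin excluded).  The fitted sill is the spatially
#' correlated part of the OmP variance and estimates the background error
#' variance; the remainder at zero distance,
#' `nugget = var_omp_zero - sill`, estimates the observation (incl.
#' representativeness) error variance.
#'
#' @param vg A `variogram_estimate` from [bin_pair_covariances].
#' @param lc_bounds Admissible correlation-length interval in km
#'   (default c(5, 500)); a fit outside it is marked failed.
#' @return The `variogram_estimate` with `fitted_sill`, `fitted_lc`,
#'   `nugget` and `fit_ok` filled in.
#' @export
fit_foar <- function(vg, lc_bounds = c(5, 500)) {
  stopifnot(inherits(vg, "variogram_estimate"))
  use <- vg$bins_used & is.finite(vg$bin_covariances)
  if (sum(use) < 3L) {
    vg$reason <- "fewer than 3 usable bins"
    return(vg)
  }
  df <- data.frame(d = vg$bin_centers[use], cv = vg$bin_covariances[use],
                   wt = vg$bin_pair_counts[use])
  start <- list(sill = max(df$cv[1], 1e-6), lc = max(df$d[1], 30))
  fit <- tryCatch(
    minpack.lm::nlsLM(cv ~ sill * exp(-d / lc), data = df, start = start,
                      weights = df$wt,
                      lower = c(1e-12, 1e-3), upper = c(Inf, 1e5),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    vg$reason <- "optimizer did not converge"
    return(vg)
  }
  p <- stats::coef(fit)
  vg$fitted_sill <- unname(p["sill"])
  vg$fitted_lc <- unname(p["lc"])
  vg$nugget <- vg$var_omp_zero - vg$fitted_sill
  if (vg$fitted_sill <= 0) {
    vg$reason <- "non-positive sill"
  } else if (vg$nugget <= 0) {
    vg$reason <- "non-positive nugget"
  } else if (vg$fitted_lc < lc_bounds[1] || vg$fitted_lc > lc_bounds[2]) {
    vg$reason <- sprintf("correlation length %.1f km outside [%g, %g]",
                         vg$fitted_lc, lc_bounds[1], lc_bounds[2])
  } else {
    vg$fit_ok <- TRUE
    vg$reason <- "ok"
  }
  vg
}

#' @export
print.variogram_estimate <- function(x, ...) {
  cat(sprintf(
    "<variogram_estimate> %d/%d bins used, varOmP(0)=%.4g\n",
    sum(x$bins_used), length(x$bin_centers), x$var_omp_zero))
  if (x$fit_ok) {
    cat(sprintf("  sill=%.4g lc=%.1f km nugget=%.4g\n",
                x$fitted_sill, x$fitted_lc, x$nugget))
  } else cat("  fit failed:", x$reason, "\n")
  invisible(x)
}

#' Observation error variance from the representativeness model
#'
#' Scales the instrument error variance up by the ratio of the effective
#' model resolution (`n * dx`, with `n = 4` by default) to four times the
#' land-use representativeness length:
#' `sigma_o2 = sigma_instr2 * (1 + n*dx / (4*L_repr))`, with `L_repr` =
#' 10, 4 and 2 km for rural, suburban and urban stations.  No tuning
#' factor is applied.
#'
#' @param sigma_instr2 Instrument error variance (> 0).
#' @param dx_km Model grid resolution in km.
#' @param land_use `"rural"`, `"suburban"` or `"urban"` (vectorized).
#' @param n Effective-resolution multiplier (default 4).
#' @return Observation error variance(s).
#' @export
obs_error_s14 <- function(sigma_instr2, dx_km, land_use, n = 4) {
  if (any(sigma_instr2 <= 0)) stop("'sigma_instr2' must be positive")
  l_repr <- c(rural = 10, suburban = 4, urban = 2)[land_use]
  if (anyNA(l_repr))
    stop("unknown land-use class: ",
         paste(unique(land_use[is.na(l_repr)]), collapse = ", "))
  unname(sigma_instr2 * (1 + n * dx_km / (4 * l_repr)))
}

#' Background error variance from the OmP residual
#'
#' The OmP variance is by definition the sum of observation and background
#' error variances, so `sigma_b2 = varOmP - sigma_o2`.  Stations where
#' the observation error already exceeds varOmP yield `NA` (flagged
#' unusable for the stratum), not an error.
#'
#' @param var_omp OmP variance(s).
#' @param sigma_o2 Observation error variance(s).
#' @return Background error variance(s); `NA` where `var_omp <= sigma_o2`.
#' @export
background_error_from_residual <- function(var_omp, sigma_o2) {
  out <- var_omp - sigma_o2
  out[out <= 0] <- NA_real_
  out
}

#' Blend the two background-error estimates
#'
#' Combines the variogram-based (HL86-style) and representativeness-based
#' estimates of the background error variance.  Both present: arithmetic
#' mean, tagged `"blended"`; one present: that one; neither: the prescribed
#' fallback.
#'
#' @param hl86_value,s14_value The two estimates (either may be `NULL` or
#'   `NA`).
#' @param prescribed Fallback value when both are missing.
#' @return List with `sigma_b2` and `source`.
#' @export
blend_sigma_b2 <- function(hl86_value = NULL, s14_value = NULL,
                           prescribed = NULL) {
  h <- if (!is.null(hl86_value) && is.finite(hl86_value)) hl86_value
  s <- if (!is.null(s14_value) && is.finite(s14_value)) s14_value
  if (!is.null(h) && !is.null(s)) {
    list(sigma_b2 = (h + s) / 2, source = "blended")
  } else if (!is.null(h)) {
    list(sigma_b2 = h, source = "HL86")
  } else if (!is.null(s)) {
    list(sigma_b2 = s, source = "S14")
  } else {
    if (is.null(prescribed)) stop("no estimate and no prescribed default")
    list(sigma_b2 = prescribed, source = "prescribed")
  }
}

#' Analysis error variance and gain ratio
#'
#' The analysis precision (inverse error variance) is the sum of the
#' background and observation precisions: `1/sigma_a2 = 1/sigma_b2 +
#' 1/sigma_o2`.  Written in terms of `lambda = sigma_b2/sigma_o2`, the
#' variance ratio is `sigma_a2/sigma_b2 = 1/(1 + lambda)`.
#'
#' @param sigma_b2,sigma_o2 Background and observation error variances.
#' @return `analysis_error_variance`: the analysis error variance
#'   `sigma_a2`.
#' @export
analysis_error_variance <- function(sigma_b2, sigma_o2) {
  if (any(sigma_b2 <= 0) || any(sigma_o2 <= 0))
    stop("variances must be positive")
  1 / (1 / sigma_b2 + 1 / sigma_o2)
}

#' @rdname analysis_error_variance
#' @param lambda_ratio Background-to-observation error variance ratio.
#' @return `analysis_error_ratio`: the ratio `sigma_a2 / sigma_b2`.
#' @export
analysis_error_ratio <- function(lambda_ratio) {
  if (any(lambda_ratio <= 0)) stop("'lambda_ratio' must be positive")
  1 / (1 + lambda_ratio)
}

#' Estimate error statistics from paired observation/forecast series
#'
#' End-to-end estimation for one pollutant stratum: per-station OmP
#' statistics, pair-covariance binning and exponential fit (variogram
#' route), the representativeness model per land-use class, blending of
#' the two background-variance estimates, and assembly of an
#' [error_stats] object with a prescribed correlation length.
#'
#' @param omp_matrix OmP matrix, hours x stations (named columns).
#' @param stations [station_set].
#' @param pollutant Pollutant name.
#' @param dx_km Model resolution in km.
#' @param sigma_instr2 Instrument error variance (default per pollutant).
#' @param lc_km Correlation length to prescribe (default per pollutant).
#' @param method `"blend"` (default), `"hl86"` or `"s14"`.
#' @param min_hours,bin_width_km,max_km,min_pairs Passed to the variogram
#'   steps.
#' @return List with `stats` (an [error_stats]) and `variogram` (the
#'   `variogram_estimate`, for inspection).
#' @export
fit_error_statistics <- function(omp_matrix, stations, pollutant,
                                 dx_km = 10,
                                 sigma_instr2 = default_sigma_instr2(pollutant),
                                 lc_km = default_lc_km(pollutant),
                                 method = c("blend", "hl86", "s14"),
                                 min_hours = 30, bin_width_km = 20,
                                 max_km = 500, min_pairs = 10) {
  method <- match.arg(method)
  ist <- compute_innovation_stats(omp_matrix, min_hours = min_hours)
  vg <- bin_pair_covariances(ist$omp, stations, bin_width_km = bin_width_km,
                             max_km = max_km, min_pairs = min_pairs)
  vg <- fit_foar(vg)

  so2_class <- obs_error_s14(sigma_instr2, dx_km,
                             c("rural", "suburban", "urban"))
  names(so2_class) <- c("rural", "suburban", "urban")

  hl86_b2 <- if (vg$fit_ok && method != "s14") vg$fitted_sill
  s14_b2 <- NULL
  if (method != "hl86") {
    st <- stations[match(names(ist$var_omp), stations$id), , drop = FALSE]
    so2_st <- so2_class[st$land_use]
    b2_st <- background_error_from_residual(ist$var_omp, so2_st)
    if (any(is.finite(b2_st))) s14_b2 <- mean(b2_st, na.rm = TRUE)
  }
  bl <- blend_sigma_b2(hl86_b2, s14_b2)
  stats <- error_stats(pollutant, sigma_b2 = bl$sigma_b2, lc_km = lc_km,
                       sigma_o2_by_class = so2_class,
                       source = bl$source)
  list(stats = stats, variogram = vg)
}
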