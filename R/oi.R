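#' Build the innovation (station-space) covariance matrix
#'
#' The optimal-interpolation gain requires the station-space covariance
#' `A = H(HB)^T + R`.  With a homogeneous, isotropic first-order
#' autoregressive (exponential) background error correlation of length
#' `Lc`, the off-diagonal entries are
#' `A[k1,k2] = sigma_f(k1) * sigma_f(k2) * exp(-d(k1,k2)/Lc)` and the
#' diagonal adds the observation error variance:
#' `A[k,k] = sigma_f(k)^2 + sigma_o(k)^2`.
#'
#' @param innov An [innovation_vector] of QC-accepted stations.
#' @param stats An [error_stats] object supplying the per-station background
#'   error standard deviation, the per-station observation error variance
#'   and the correlation length.
#' @return Symmetric positive-definite matrix of dimension
#'   `length(innov) x length(innov)` with attributes `sigma_f` and
#'   `sigma_o2` (the per-station values used).
#' @export
build_innovation_matrix <- function(innov, stats) {
  st <- innov$stations
  n <- nrow(st)
  if (n == 0L) stop("no stations in innovation vector")
  sf <- station_sigma_f(stats, st$id)
  so2 <- station_sigma_o2(stats, st$id, st$land_use)
  if (any(sf <= 0) || any(so2 <= 0) || stats$lc_km <= 0)
    stop("error statistics must be strictly positive")
  dmat <- distance_matrix_km(st$lat, st$lon)
  if (n > 1L && min(dmat[upper.tri(dmat)]) <= 0)
    stop("stations at identical coordinates; merge them before matrix build")
  A <- outer(sf, sf) * exp(-dmat / stats$lc_km)
  diag(A) <- sf^2 + so2
  attr(A, "sigma_f") <- sf
  attr(A, "sigma_o2") <- so2
  A
}

#' Solve for the observation weights
#'
#' Solves `A w = d` by Cholesky factorization.  If the factorization fails,
#' a single jitter of `1e-8 * trace(A)/n` is added to the diagonal and the
#' solve is retried; a second failure is a hard error naming the closest
#' station pair (the usual culprit).
#'
#' @param A Innovation matrix from [build_innovation_matrix].
#' @param d Innovations (observation minus forecast at the stations).
#' @param innov Optional [innovation_vector], used only to name stations in
#'   the failure message.
#' @return Weight vector `w` with `A %*% w = d`.
#' @export
solve_weights <- function(A, d, innov = NULL) {
  stopifnot(nrow(A) == length(d))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-8 * sum(diag(A)) / nrow(A)
    ch <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (is.null(ch)) {
      pair <- "unknown"
      if (!is.null(innov) && length(innov) > 1L) {
        st <- innov$stations
        dm <- distance_matrix_km(st$lat, st$lon)
        diag(dm) <- Inf
        ij <- arrayInd(which.min(dm), dim(dm))
        pair <- paste(st$id[ij[1]], st$id[ij[2]], sep = " / ")
      }
      stop("innovation matrix not positive definite even after jitter; ",
           "closest station pair: ", pair)
    }
  }
  backsolve(ch, forwardsolve(t(ch), d))
}

#' Spread weighted innovations onto the grid
#'
#' Applies the gain: the analysis increment at grid cell (i,j) is
#' `sum_k sigma_f_grid * sigma_f(k) * exp(-d((i,j),k)/Lc) * w[k]`, i.e. the
#' cross-covariance row `(HB)^T` times the weights.  The grid-side
#' background error standard deviation is the homogeneous domain value;
#' the station-side values are local.
#'
#' @param forecast Forecast [grid_field] (first guess).
#' @param innov [innovation_vector] used for the analysis.
#' @param w Weights from [solve_weights].
#' @param stats [error_stats].
#' @return An `analysis_product`: list with `forecast`, `analysis`,
#'   `increment` grid fields and the `innovations` used.
#' @export
apply_gain <- function(forecast, innov, w, stats) {
  stopifnot(inherits(forecast, "grid_field"))
  if (!identical(forecast$pollutant, innov$pollutant))
    stop("forecast pollutant (", forecast$pollutant,
         ") does not match innovations (", innov$pollutant, ")")
  if (!isTRUE(all.equal(forecast$valid_time, innov$valid_time)))
    stop("forecast and innovation valid times differ")
  st <- innov$stations
  sf_k <- station_sigma_f(stats, st$id)
  sf_grid <- sqrt(stats$sigma_b2)
  nlat <- length(forecast$lats); nlon <- length(forecast$lons)
  glat <- rep(forecast$lats, times = nlon)
  glon <- rep(forecast$lons, each = nlat)
  inc <- numeric(nlat * nlon)
  for (k in seq_len(nrow(st))) {
    dk <- great_circle_km(glat, glon, st$lat[k], st$lon[k])
    inc <- inc + sf_grid * sf_k[k] * exp(-dk / stats$lc_km) * w[k]
  }
  increment <- matrix(inc, nlat, nlon)
  ana <- forecast
  ana$values <- forecast$values + increment
  incf <- forecast
  incf$values <- increment
  structure(list(forecast = forecast, analysis = ana, increment = incf,
                 innovations = innov),
            class = "analysis_product")
}

#' @export
print.analysis_product <- function(x, ...) {
  cat(sprintf("<analysis_product> %s, %d observations assimilated\n",
              x$forecast$pollutant, length(x$innovations)))
  if (!is.null(x$qc_counts)) {
    cat("  QC: ", paste(names(x$qc_counts), x$qc_counts, sep = "=",
                        collapse = ", "), "\n")
  }
  inc <- x$increment$values
  cat(sprintf("  increment range [%.3g, %.3g], mean %.3g\n",
              min(inc), max(inc), mean(inc)))
  invisible(x)
}

#' Full single-hour objective analysis
#'
#' Runs the complete chain for one pollutant at one hour: quality control
#' of the observations, optional regional bias correction of the forecast,
#' innovation computation (bilinear forecast interpolation), co-located
#' station merging, innovation-matrix build and Cholesky solve, and the
#' gain application.  If every observation is rejected the (bias-corrected)
#' forecast is returned as the analysis with a warning.
#'
#' @param forecast Forecast [grid_field].
#' @param observations Data frame with columns `station_id`, `value` (one
#'   record per station for this hour), or an already QC-flagged table.
#' @param stations [station_set] describing the stations.
#' @param stats [error_stats] for the pollutant/stratum.
#' @param qc_config QC thresholds from [qc_config()]; `NULL` skips QC.
#' @param bias_regions Optional list of [bias_region] objects; when given,
#'   regional mean biases are estimated from the innovations and the
#'   forecast is corrected before the OI update.
#' @return An `analysis_product`; element `qc_counts` records how many
#'   records each QC stage rejected, element `bias` the per-region
#'   corrections applied.
#' @export
analyze <- function(forecast, observations, stations, stats,
                    qc_config = NULL, bias_regions = NULL) {
  stopifnot(inherits(forecast, "grid_field"))
  obs <- observations
  obs$station_id <- as.character(obs$station_id)
  obs <- obs[match(obs$station_id, stations$id, nomatch = 0L) > 0L, ,
             drop = FALSE]
  st <- stations[match(obs$station_id, stations$id), , drop = FALSE]

  h_xf <- interpolate_to_stations(forecast, st)
  outside <- attr(h_xf, "outside")
  if (length(outside)) {
    message(length(outside), " station(s) outside the grid dropped: ",
            paste(utils::head(st$id[outside], 5L), collapse = ", "))
    keep <- setdiff(seq_len(nrow(st)), outside)
    obs <- obs[keep, , drop = FALSE]
    st <- st[keep, , drop = FALSE]
    h_xf <- h_xf[keep]
  }

  qc_counts <- c(total = nrow(obs), RANGE = 0L, JUMP = 0L, BGCK = 0L,
                 accepted = nrow(obs))
  accepted <- rep(TRUE, nrow(obs))
  if (!is.null(qc_config)) {
    flagged <- qc_chain(cbind(obs, h_xf = h_xf, land_use = st$land_use),
                        forecast$pollutant, stats, qc_config)
    accepted <- flagged$accepted
    qc_counts["RANGE"] <- sum(grepl("RANGE", flagged$qc_flags))
    qc_counts["JUMP"] <- sum(grepl("JUMP", flagged$qc_flags))
    qc_counts["BGCK"] <- sum(grepl("BGCK", flagged$qc_flags))
    qc_counts["accepted"] <- sum(accepted)
  }
  obs <- obs[accepted, , drop = FALSE]
  st <- st[accepted, , drop = FALSE]
  h_xf <- h_xf[accepted]

  # regional bias correction is applied to the forecast before the OI update
  bias <- NULL
  if (!is.null(bias_regions) && nrow(obs) > 0L) {
    innov0 <- innovation_vector(st, obs$value, h_xf, forecast$pollutant,
                                forecast$valid_time)
    bias <- vapply(bias_regions, function(r)
      estimate_regional_bias(innov0, r), numeric(1))
    forecast <- apply_bias_field(forecast, bias_regions, bias)
    h_xf <- interpolate_to_stations(forecast, st)
  }

  if (nrow(obs) == 0L) {
    warning("no observations accepted; analysis equals the forecast")
    empty <- innovation_vector(st, numeric(0), numeric(0),
                               forecast$pollutant, forecast$valid_time)
    inc <- forecast; inc$values <- forecast$values * 0
    prod <- structure(list(forecast = forecast, analysis = forecast,
                           increment = inc, innovations = empty),
                      class = "analysis_product")
    prod$qc_counts <- qc_counts
    prod$bias <- bias
    return(prod)
  }

  innov <- innovation_vector(st, obs$value, h_xf, forecast$pollutant,
                             forecast$valid_time)
  innov <- merge_colocated(innov)
  A <- build_innovation_matrix(innov, stats)
  w <- solve_weights(A, innov$d, innov)
  prod <- apply_gain(forecast, innov, w, stats)
  prod$qc_counts <- qc_counts
  prod$bias <- bias
  prod
}
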