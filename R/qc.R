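#' Quality-control configuration
#'
#' Thresholds for the three-stage observation quality control.  All
#' defaults are configurable stand-ins: plausible operating values for the
#' range limits, hourly jump limits and the background-check multiplier
#' `k`.  Equality with a threshold passes; only strict exceedance flags.
#'
#' @param range_limits Named list of `c(min, max)` per pollutant.
#' @param jump_limits Named vector of maximum absolute hour-to-hour changes.
#' @param k_bgck Background-check multiplier: flag when
#'   `|O - P| > k * sqrt(sigma_b2 + sigma_o2)` (default 4).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(range_limits = list(O3 = c(0, 250), NO2 = c(0, 200),
                                          "PM2.5" = c(0, 500),
                                          PM10 = c(0, 1000)),
                      jump_limits = c(O3 = 50, NO2 = 60, "PM2.5" = 100,
                                      PM10 = 200),
                      k_bgck = 4) {
  structure(list(range_limits = range_limits, jump_limits = jump_limits,
                 k_bgck = k_bgck), class = "qc_config")
}

#' Range check
#'
#' Flags records whose value falls strictly outside the configured
#' minimum/maximum concentration for the pollutant.
#'
#' @param values Numeric vector of concentrations.
#' @param pollutant Pollutant name.
#' @param config A [qc_config].
#' @return Logical vector, `TRUE` where the RANGE flag applies.
#' @export
range_check <- function(values, pollutant, config = qc_config()) {
  lim <- config$range_limits[[pollutant]]
  if (is.null(lim)) stop("no range limits configured for ", pollutant)
  values < lim[1] | values > lim[2]
}

#' Hourly jump check
#'
#' Flags records whose absolute difference from the previous valid hour
#' strictly exceeds the configured jump limit.  The first record of a
#' series is never flagged, and the check is not applied across gaps
#' (missing hours) in the series.
#'
#' @param values Hourly concentration series for one station, time-sorted.
#' @param times Integer (or integer-valued) hour stamps aligned with
#'   `values`; consecutive means `diff(times) == 1`.  `NULL` treats the
#'   series as gap-free.
#' @param pollutant Pollutant name.
#' @param config A [qc_config].
#' @return Logical vector, `TRUE` where the JUMP flag applies.
#' @export
jump_check <- function(values, times = NULL, pollutant,
                       config = qc_config()) {
  lim <- config$jump_limits[[pollutant]]
  if (is.null(lim) || is.na(lim)) stop("no jump limit configured for ", pollutant)
  n <- length(values)
  flag <- rep(FALSE, n)
  if (n < 2L) return(flag)
  dv <- abs(diff(values))
  consecutive <- if (is.null(times)) rep(TRUE, n - 1L) else
    diff(as.numeric(times)) == 1
  flag[-1L] <- dv > lim & consecutive
  flag
}

#' Background check
#'
#' Flags records whose innovation magnitude strictly exceeds
#' `k * sqrt(sigma_b2 + sigma_o2)`: such an observation is too far from
#' the forecast to be explained by the combined error budget.
#'
#' @param values Observed concentrations.
#' @param forecast_at_station Forecast interpolated to the stations.
#' @param sigma_b2 Background error variance (scalar).
#' @param sigma_o2 Observation error variance (scalar or per record).
#' @param k Multiplier (default 4).
#' @return Logical vector, `TRUE` where the BGCK flag applies.
#' @export
background_check <- function(values, forecast_at_station, sigma_b2,
                             sigma_o2, k = 4) {
  abs(values - forecast_at_station) > k * sqrt(sigma_b2 + sigma_o2)
}

#' Run the full QC chain on an observation table
#'
#' Applies range, jump and background checks in order.  Every record is
#' run through all three stages (flags accumulate for reporting); any flag
#' rejects the record.  QC only flags, never modifies values, and is
#' idempotent.
#'
#' @param obs Data frame with columns `station_id`, `value`, and optionally
#'   `time` (hour stamps, needed for the jump check), `h_xf` (forecast at
#'   station, needed for the background check) and `land_use`.
#' @param pollutant Pollutant name.
#' @param stats Optional [error_stats]; without it the background check is
#'   skipped with a warning.
#' @param config A [qc_config].
#' @return `obs` with added columns `qc_flags` (comma-separated flag names,
#'   `""` if clean) and `accepted`.
#' @export
qc_chain <- function(obs, pollutant, stats = NULL, config = qc_config()) {
  n <- nrow(obs)
  fr <- range_check(obs$value, pollutant, config)
  fj <- rep(FALSE, n)
  if (!is.null(obs$time)) {
    for (sid in unique(obs$station_id)) {
      i <- which(obs$station_id == sid)
      i <- i[order(obs$time[i])]
      fj[i] <- jump_check(obs$value[i], obs$time[i], pollutant, config)
    }
  }
  fb <- rep(FALSE, n)
  if (!is.null(obs$h_xf)) {
    if (is.null(stats)) {
      warning("no error statistics supplied; background check skipped")
    } else {
      so2 <- if (!is.null(obs$land_use))
        station_sigma_o2(stats, obs$station_id, obs$land_use)
      else mean(c(stats$sigma_o2_by_station, stats$sigma_o2_by_class))
      fb <- background_check(obs$value, obs$h_xf, stats$sigma_b2, so2,
                             config$k_bgck)
      fb[is.na(fb)] <- FALSE
    }
  }
  flags <- character(n)
  flags[fr] <- "RANGE"
  flags[fj] <- ifelse(nzchar(flags[fj]), paste0(flags[fj], ",JUMP"), "JUMP")
  flags[fb] <- ifelse(nzchar(flags[fb]), paste0(flags[fb], ",BGCK"), "BGCK")
  obs$qc_flags <- flags
  obs$accepted <- !nzchar(flags)
  obs
}
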