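#' Air Quality Health Index
#'
#' The Canadian AQHI combines NO2, O3 (ppbv) and PM2.5 (ug/m3) into a
#' unitless health-risk index:
#' `AQHI = (10/10.4) * 100 * [(e^(0.000871*NO2) - 1) + (e^(0.000537*O3) - 1)
#'  + (e^(0.000487*PM2.5) - 1)]`.
#' Official reporting uses 3-h running mean concentrations as inputs; the
#' function itself is pointwise and vectorized.
#'
#' @param no2,o3,pm25 Non-negative concentrations (NO2 and O3 in ppbv,
#'   PM2.5 in ug/m3); vectors recycle.
#' @return Real-valued AQHI, strictly increasing in each argument.
#' @export
aqhi_exact <- function(no2, o3, pm25) {
  if (any(no2 < 0, o3 < 0, pm25 < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  (10 / 10.4) * 100 * ((exp(0.000871 * no2) - 1) +
                       (exp(0.000537 * o3) - 1) +
                       (exp(0.000487 * pm25) - 1))
}

#' Linearized AQHI
#'
#' First-order approximation `exp(x) ~ 1 + x` of [aqhi_exact], turning the
#' index into a linear combination of the three pollutants weighted by
#' their risk factors: `(0.871*NO2 + 0.537*O3 + 0.487*PM2.5) / 10.4`.
#' For balanced mixtures with exact AQHI up to 10 the relative error of
#' the linear form stays below 2%.
#'
#' @inheritParams aqhi_exact
#' @return Linearized AQHI.
#' @export
aqhi_linear <- function(no2, o3, pm25) {
  if (any(no2 < 0, o3 < 0, pm25 < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  (0.871 * no2 + 0.537 * o3 + 0.487 * pm25) / 10.4
}

#' AQHI health-risk category
#'
#' Rounds the index to the nearest integer (half away from zero, floored
#' at 1, the reporting convention) and maps it to the standard bands:
#' 1-3 Low, 4-6 Moderate, 7-10 High, above 10 Extreme.
#'
#' @param aqhi Non-negative AQHI value(s).
#' @return Factor with levels `Low`, `Moderate`, `High`, `Extreme`.
#' @export
aqhi_category <- function(aqhi) {
  if (any(aqhi < 0, na.rm = TRUE)) stop("AQHI must be non-negative")
  r <- pmax(1, floor(aqhi + 0.5))
  lab <- ifelse(r <= 3, "Low",
         ifelse(r <= 6, "Moderate",
         ifelse(r <= 10, "High", "Extreme")))
  factor(lab, levels = c("Low", "Moderate", "High", "Extreme"))
}

#' Trailing 3-hour running mean
#'
#' Mean of the current and two previous hours.  A window containing any
#' missing hour yields `NA`; the first two positions are always `NA`.
#'
#' @param x Hourly series (numeric; `NA` for missing hours).
#' @return Series of the same length.
#' @export
rolling_3h <- function(x) {
  n <- length(x)
  if (n < 3L) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  out[3:n] <- (x[3:n] + x[2:(n - 1)] + x[1:(n - 2)]) / 3
  out
}

#' Gridded AQHI pseudo-analysis
#'
#' Applies the exact AQHI formula cellwise to three co-registered
#' pollutant analyses.  Because the index is computed from objective
#' analyses rather than assimilated from AQHI observations, the product is
#' a pseudo objective analysis; in place of an analysis increment it
#' carries a residual grid, here the exact-minus-linear index difference
#' (the local size of the linearization term).
#'
#' @param no2,o3,pm25 Co-registered [grid_field] analyses for the same
#'   hour.
#' @return List with `aqhi` (a [grid_field], pollutant `"AQHI"`) and
#'   `residual` (exact minus linear index, same grid).
#' @export
aqhi_map <- function(no2, o3, pm25) {
  stopifnot(inherits(no2, "grid_field"), inherits(o3, "grid_field"),
            inherits(pm25, "grid_field"))
  if (!same_grid(no2, o3) || !same_grid(no2, pm25))
    stop("the three analyses must share the same grid")
  if (!isTRUE(all.equal(no2$valid_time, o3$valid_time)) ||
      !isTRUE(all.equal(no2$valid_time, pm25$valid_time)))
    stop("the three analyses must share the same valid time")
  ex <- aqhi_exact(no2$values, o3$values, pm25$values)
  li <- aqhi_linear(no2$values, o3$values, pm25$values)
  aq <- grid_field(no2$lats, no2$lons, ex, "AQHI",
                   valid_time = no2$valid_time, dx_km = no2$dx_km)
  res <- aq
  res$values <- ex - li
  list(aqhi = aq, residual = res)
}

#' Seasonal AQHI exceedance climatology
#'
#' For each cell and season, the percentage of valid hours with AQHI
#' strictly above the threshold.  Cells below `floor_pct` are floored to 0
#' (rendered as plain background in maps); cells with no valid hours are
#' `NA`.
#'
#' @param aqhi_series List of AQHI [grid_field]s on a common grid.
#' @param months Integer month (1-12) of each grid in `aqhi_series`.
#' @param threshold Exceedance threshold (default 3, the lower bound of
#'   moderate health risk).
#' @param floor_pct Report floor in percent (default 1); frequencies below
#'   it are reported as 0 (effectively unpolluted).
#' @return Named list of percentage matrices, one per season
#'   (`DJF`, `MAM`, `JJA`, `SON`) present in the data.
#' @export
exceedance_climatology <- function(aqhi_series, months, threshold = 3,
                                   floor_pct = 1) {
  stopifnot(length(aqhi_series) == length(months))
  if (!length(aqhi_series)) stop("empty AQHI series")
  season_of <- function(m) c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
                             "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  seas <- season_of(months)
  out <- list()
  for (s in intersect(c("DJF", "MAM", "JJA", "SON"), unique(seas))) {
    idx <- which(seas == s)
    exceed <- valid <- 0 * aqhi_series[[idx[1]]]$values
    for (i in idx) {
      v <- aqhi_series[[i]]$values
      exceed <- exceed + (!is.na(v) & v > threshold)
      valid <- valid + !is.na(v)
    }
    pct <- 100 * exceed / valid
    pct[valid == 0] <- NA_real_
    pct[!is.na(pct) & pct < floor_pct] <- 0
    out[[s]] <- pct
  }
  out
}
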