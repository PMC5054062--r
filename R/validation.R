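#' Verification metrics
#'
#' Mean bias, standard deviation of the residual, and the frequency of
#' being correct within a factor of two (FC2).  Bias and std use
#' observation-minus-prediction; FC2 counts pairs with
#' `0.5 <= P/O <= 2` (inclusive) among pairs whose observed value is at
#' least `floor` (ratios are unstable near zero).
#'
#' @param observed,predicted Paired numeric vectors.
#' @param floor Minimum observed value entering FC2 (default 1
#'   concentration unit).
#' @return List with `mean_bias`, `std`, `fc2`, `n_pairs` and `n_fc2`.
#' @export
validation_metrics <- function(observed, predicted, floor = 1) {
  ok <- is.finite(observed) & is.finite(predicted)
  if (!any(ok)) stop("no valid observation/prediction pairs")
  o <- observed[ok]; p <- predicted[ok]
  resid <- o - p
  use <- o >= floor
  fc2 <- if (any(use)) {
    ratio <- p[use] / o[use]
    mean(ratio >= 0.5 & ratio <= 2)
  } else NA_real_
  list(mean_bias = mean(resid),
       std = if (length(resid) > 1L) stats::sd(resid) else 0,
       fc2 = fc2, n_pairs = length(resid), n_fc2 = sum(use))
}

#' Random station splits for cross-validation
#'
#' Splits the station set into analysis and holdout subsets by station
#' (holdout series are wholly unseen by the analysis), with independent
#' seeded replicates.
#'
#' @param stations [station_set] or data frame with an `id` column.
#' @param fraction Fraction of stations used for the analysis (0.9 for the
#'   densely observed pollutants, 0.75 for the sparser ones).
#' @param n_replicates Number of independent splits (default 3).
#' @param seed Integer seed; replicate `r` uses `seed + r - 1`.
#' @return List of splits, each a list with `analysis_ids`, `holdout_ids`,
#'   `fraction`, `replicate`, `seed`.
#' @export
make_splits <- function(stations, fraction = 0.9, n_replicates = 3,
                        seed = 1) {
  ids <- as.character(stations$id)
  n <- length(ids)
  n_analysis <- round(fraction * n)
  if (n_analysis >= n || n_analysis < 1L)
    stop("split leaves an empty analysis or holdout set")
  lapply(seq_len(n_replicates), function(r) {
    set.seed(seed + r - 1L)
    a <- sort(sample(ids, n_analysis))
    list(analysis_ids = a, holdout_ids = setdiff(ids, a),
         fraction = fraction, replicate = r, seed = seed + r - 1L)
  })
}

#' Verification-region labels
#'
#' Partitions stations into eastern/western Canada and USA, splitting
#' east from west at longitude 90 degrees W (a longitude of exactly -90
#' counts as East).  Stations without a country label get `"all"`.
#'
#' @param stations Data frame with `lon` and optionally `country`
#'   (`"Canada"` or `"USA"`).
#' @return Character vector of labels (`E-Canada`, `W-Canada`, `E-USA`,
#'   `W-USA`, or `all`).
#' @export
regional_partition <- function(stations) {
  if (is.null(stations$country)) return(rep("all", nrow(stations)))
  ew <- ifelse(stations$lon < -90, "W", "E")
  out <- ifelse(is.na(stations$country), "all",
                paste0(ew, "-", stations$country))
  out[!out %in% c("E-Canada", "W-Canada", "E-USA", "W-USA")] <- "all"
  out
}

#' Internal validation of an analysis product
#'
#' Compares the assimilated observations with the forecast (OmP) and with
#' the analysis (OmA) at the same stations.
#'
#' @param product An `analysis_product`.
#' @param floor FC2 observation floor.
#' @return Data frame with one row of OmP metrics and one of OmA metrics.
#' @export
internal_validation <- function(product, floor = 1) {
  innov <- product$innovations
  h_xa <- interpolate_to_stations(product$analysis, innov$stations)
  mp <- validation_metrics(innov$y_o, innov$h_xf, floor)
  ma <- validation_metrics(innov$y_o, h_xa, floor)
  data.frame(quantity = c("OmP", "OmA"),
             mean_bias = c(mp$mean_bias, ma$mean_bias),
             std = c(mp$std, ma$std),
             fc2 = c(mp$fc2, ma$fc2),
             n_pairs = c(mp$n_pairs, ma$n_pairs))
}

#' Station-holdout cross-validation of the objective analysis
#'
#' For each replicate split, analyses are produced from the analysis
#' stations only and evaluated at the holdout stations, where both the
#' forecast (OmP) and the analysis (OmA) errors are recorded.  The
#' replicates' pairs are pooled per UTC hour before metrics and
#' significance tests: a two-sided unpaired t-test compares the mean of
#' OmP vs OmA and a two-sided F-test compares their variances; hours with
#' p below `alpha` are flagged significant.
#'
#' @param scene A synthetic (or assembled) scene: list with elements
#'   `forecasts` (list of [grid_field], one per hour), `obs` (data frame
#'   `station_id`, `time`, `value`), `stations` ([station_set]).
#' @param stats [error_stats] used for the analyses.
#' @param fraction Analysis fraction of stations (default 0.9).
#' @param n_replicates Number of splits pooled (default 3).
#' @param seed Split seed.
#' @param qc_cfg Optional [qc_config] applied inside [analyze].
#' @param bias_regions Optional list of [bias_region]s.
#' @param floor FC2 observation floor.
#' @param alpha Significance level (default 0.05).
#' @param min_pairs Minimum pooled pairs per hour for testing (default 10).
#' @return Object of class `validation_report`: data frame `by_hour` with
#'   per-UTC-hour metrics and p-values, plus the pooled pair table
#'   `pairs`.
#' @export
cross_validate <- function(scene, stats, fraction = 0.9, n_replicates = 3,
                           seed = 1, qc_cfg = NULL, bias_regions = NULL,
                           floor = 1, alpha = 0.05, min_pairs = 10) {
  splits <- make_splits(scene$stations, fraction, n_replicates, seed)
  hours <- sort(unique(scene$obs$time))
  pairs <- list()
  for (sp in splits) {
    hold <- scene$stations[scene$stations$id %in% sp$holdout_ids, ,
                           drop = FALSE]
    for (h in seq_along(hours)) {
      fc <- scene$forecasts[[h]]
      obs_h <- scene$obs[scene$obs$time == hours[h], , drop = FALSE]
      obs_a <- obs_h[obs_h$station_id %in% sp$analysis_ids, , drop = FALSE]
      prod <- analyze(fc, obs_a,
                      scene$stations[scene$stations$id %in% sp$analysis_ids, ,
                                     drop = FALSE],
                      stats, qc_config = qc_cfg,
                      bias_regions = bias_regions)
      obs_v <- obs_h[obs_h$station_id %in% sp$holdout_ids, , drop = FALSE]
      hv <- hold[match(obs_v$station_id, hold$id), , drop = FALSE]
      h_xf <- interpolate_to_stations(prod$forecast, hv)
      h_xa <- interpolate_to_stations(prod$analysis, hv)
      ok <- is.finite(h_xf) & is.finite(h_xa)
      if (!any(ok)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        hour = hours[h], replicate = sp$replicate,
        station_id = obs_v$station_id[ok],
        observed = obs_v$value[ok], forecast = h_xf[ok],
        analysis = h_xa[ok])
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("cross-validation produced no holdout pairs")
  by_hour <- lapply(split(pairs, pairs$hour), function(ph) {
    mp <- validation_metrics(ph$observed, ph$forecast, floor)
    ma <- validation_metrics(ph$observed, ph$analysis, floor)
    omp <- ph$observed - ph$forecast
    oma <- ph$observed - ph$analysis
    p_mean <- p_var <- NA_real_
    if (nrow(ph) >= min_pairs) {
      p_mean <- stats::t.test(omp, oma)$p.value
      p_var <- stats::var.test(omp, oma)$p.value
    }
    data.frame(hour = ph$hour[1], n_pairs = nrow(ph),
               mean_omp = mp$mean_bias, mean_oma = ma$mean_bias,
               std_omp = mp$std, std_oma = ma$std,
               fc2_model = mp$fc2, fc2_analysis = ma$fc2,
               p_mean = p_mean, p_var = p_var,
               significant_var = is.finite(p_var) & p_var < alpha,
               significant_mean = is.finite(p_mean) & p_mean < alpha)
  })
  by_hour <- do.call(rbind, by_hour)
  rownames(by_hour) <- NULL
  structure(list(by_hour = by_hour, pairs = pairs,
                 pollutant = stats$pollutant, mode = "cross",
                 fraction = fraction, n_replicates = n_replicates,
                 seed = seed, alpha = alpha),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s, %s validation, %d hours, %d pooled pairs\n",
    x$pollutant, x$mode, nrow(x$by_hour), nrow(x$pairs)))
  cat(sprintf("  mean std(OmP)=%.3f -> std(OmA)=%.3f; F-test significant %d/%d hours\n",
              mean(x$by_hour$std_omp), mean(x$by_hour$std_oma),
              sum(x$by_hour$significant_var, na.rm = TRUE),
              nrow(x$by_hour)))
  invisible(x)
}
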