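test_that("per-station OmP statistics behave as designed", {
  # forecast == obs -> zero variance everywhere
  omp0 <- matrix(0, 50, 4, dimnames = list(NULL, paste0("S", 1:4)))
  ist0 <- compute_innovation_stats(omp0)
  expect_equal(unname(ist0$var_omp), rep(0, 4))
  # constant offset -> mean 5, variance 0
  ist5 <- compute_innovation_stats(omp0 + 5)
  expect_equal(unname(ist5$mean_omp), rep(5, 4))
  expect_equal(unname(ist5$var_omp), rep(0, 4))
  # white noise of variance 25 over 1000 hours
  set.seed(21)
  ompn <- matrix(rnorm(1000 * 6, 0, 5), 1000, 6,
                 dimnames = list(NULL, paste0("S", 1:6)))
  istn <- compute_innovation_stats(ompn)
  expect_equal(mean(istn$var_omp), 25, tolerance = 0.1)
  # short series are excluded
  omp_short <- omp0
  omp_short[11:50, 2] <- NA
  expect_false("S2" %in% colnames(compute_innovation_stats(omp_short)$omp))
  expect_error(compute_innovation_stats(matrix(NA_real_, 5, 2)), "empty")
})

test_that("pair covariances recover the generating spatial structure", {
  st <- toy_stations(n = 40, seed = 13)
  # identical series at every station: every pair covariance = varOmP
  set.seed(22)
  base <- rnorm(200, 0, 3)
  omp_same <- matrix(base, 200, 40, dimnames = list(NULL, st$id))
  vg <- bin_pair_covariances(omp_same, st, bin_width_km = 40, max_km = 400,
                             min_pairs = 5)
  used <- vg$bins_used
  expect_equal(vg$bin_covariances[used],
               rep(var(base), sum(used)), tolerance = 1e-10)
  # independent series: covariances near zero
  set.seed(23)
  omp_ind <- matrix(rnorm(1000 * 40, 0, 3), 1000, 40,
                    dimnames = list(NULL, st$id))
  vg_i <- bin_pair_covariances(omp_ind, st, bin_width_km = 40,
                               max_km = 400, min_pairs = 5)
  expect_lt(max(abs(vg_i$bin_covariances[vg_i$bins_used])), 0.5)
  # correlated draws with covariance 25 * exp(-d/60): bins track the curve
  set.seed(24)
  dm <- distance_matrix_km(st$lat, st$lon)
  C <- 25 * exp(-dm / 60)
  z <- matrix(rnorm(2000 * 40), 2000, 40) %*% chol(C)
  colnames(z) <- st$id
  vg_c <- bin_pair_covariances(z, st, bin_width_km = 40, max_km = 400,
                               min_pairs = 8)
  model_all <- 25 * exp(-vg_c$bin_centers / 60)
  use <- vg_c$bins_used & model_all > 2  # bins where signal dominates noise
  model <- model_all[use]
  expect_true(all(abs(vg_c$bin_covariances[use] - model) / model < 0.15))
})

test_that("the exponential fit recovers exact inputs and flags bad ones", {
  st <- toy_stations(n = 30, seed = 14)
  omp <- matrix(rnorm(100 * 30), 100, 30, dimnames = list(NULL, st$id))
  vg <- bin_pair_covariances(omp, st, bin_width_km = 40, max_km = 400,
                             min_pairs = 5)
  # overwrite bins with a noiseless exponential: exact recovery
  vg$bin_covariances <- 25 * exp(-vg$bin_centers / 60)
  vg$bins_used <- rep(TRUE, length(vg$bin_centers))
  vg$bin_pair_counts <- rep(50L, length(vg$bin_centers))
  vg$var_omp_zero <- 34
  fit <- fit_foar(vg)
  expect_true(fit$fit_ok)
  expect_equal(fit$fitted_sill, 25, tolerance = 1e-6)
  expect_equal(fit$fitted_lc, 60, tolerance = 1e-6)
  expect_equal(fit$nugget, 34 - fit$fitted_sill, tolerance = 1e-6)
  # nugget must be positive: var_omp_zero below the sill fails the fit
  vg_bad <- vg
  vg_bad$var_omp_zero <- 20
  expect_false(fit_foar(vg_bad)$fit_ok)
  # too few bins
  vg_few <- vg
  vg_few$bins_used <- c(TRUE, TRUE, rep(FALSE, length(vg$bin_centers) - 2))
  expect_match(fit_foar(vg_few)$reason, "3 usable bins")
})

test_that("representativeness model scales instrument error by land use", {
  expect_equal(obs_error_s14(4, 10, "rural"), 8)
  expect_equal(obs_error_s14(4, 10, "suburban"), 14)
  expect_equal(obs_error_s14(4, 10, "urban"), 24)
  # dx -> 0 recovers the bare instrument error
  expect_equal(obs_error_s14(4, 1e-12, "urban"), 4, tolerance = 1e-9)
  # monotone: larger representativeness length, smaller error
  v <- obs_error_s14(4, 10, c("rural", "suburban", "urban"))
  expect_true(all(diff(v) > 0))
  expect_error(obs_error_s14(4, 10, "industrial"), "land-use")
  expect_error(obs_error_s14(-1, 10, "rural"), "positive")
})

test_that("residual decomposition and blending behave as documented", {
  expect_equal(background_error_from_residual(34, 9), 25)
  expect_true(is.na(background_error_from_residual(8, 9)))
  b <- blend_sigma_b2(20, 30)
  expect_equal(b$sigma_b2, 25)
  expect_identical(b$source, "blended")
  expect_identical(blend_sigma_b2(NULL, 30)$source, "S14")
  expect_equal(blend_sigma_b2(20, NULL)$sigma_b2, 20)
  expect_identical(blend_sigma_b2(prescribed = 12)$source, "prescribed")
  # blending is bounded by its inputs
  set.seed(31)
  for (i in 1:20) {
    x <- runif(2, 1, 50)
    bb <- blend_sigma_b2(x[1], x[2])$sigma_b2
    expect_true(bb >= min(x) && bb <= max(x))
  }
})

test_that("analysis error relations are mutually consistent", {
  # lambda = 2: background variance cut by a factor of 3
  expect_equal(1 / analysis_error_ratio(2), 3)
  expect_equal(analysis_error_variance(16, 9), 5.76)
  # precision-sum and lambda forms agree for all positive inputs
  set.seed(32)
  for (i in 1:50) {
    b2 <- runif(1, 0.1, 100); o2 <- runif(1, 0.1, 100)
    expect_equal(analysis_error_variance(b2, o2),
                 b2 * analysis_error_ratio(b2 / o2), tolerance = 1e-12)
    expect_lt(analysis_error_variance(b2, o2), min(b2, o2))
  }
  # sigma_o -> Inf leaves the background variance
  expect_equal(analysis_error_variance(16, 1e12), 16, tolerance = 1e-9)
  expect_error(analysis_error_ratio(-1), "positive")
})

test_that("HL86 + S14 consistency: sill + nugget reproduces varOmP", {
  st <- toy_stations(n = 25, seed = 15)
  set.seed(33)
  dm <- distance_matrix_km(st$lat, st$lon)
  C <- 20 * exp(-dm / 80) + diag(10, 25)
  z <- matrix(rnorm(800 * 25), 800, 25) %*% chol(C)
  colnames(z) <- st$id
  ist <- compute_innovation_stats(z)
  vg <- bin_pair_covariances(ist$omp, st, bin_width_km = 40, max_km = 400,
                             min_pairs = 5)
  vg <- fit_foar(vg)
  expect_true(vg$fit_ok)
  # the nugget is defined as varOmP(0) - sill: identity holds exactly
  expect_equal(vg$fitted_sill + vg$nugget, vg$var_omp_zero,
               tolerance = 1e-10)
})

test_that("fit_error_statistics assembles a usable error_stats object", {
  st <- toy_stations(n = 30, seed = 16)
  set.seed(34)
  dm <- distance_matrix_km(st$lat, st$lon)
  C <- 25 * exp(-dm / 60) + diag(12, 30)
  z <- matrix(rnorm(600 * 30), 600, 30) %*% chol(C)
  colnames(z) <- st$id
  out <- fit_error_statistics(z, st, "O3", dx_km = 10, sigma_instr2 = 4,
                              bin_width_km = 40, max_km = 400,
                              min_pairs = 5)
  expect_s3_class(out$stats, "error_stats")
  expect_true(out$stats$sigma_b2 > 0)
  expect_identical(out$stats$lc_km, 60)
  expect_true(out$stats$source %in% c("HL86", "S14", "blended"))
  expect_named(out$stats$sigma_o2_by_class,
               c("rural", "suburban", "urban"))
})
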