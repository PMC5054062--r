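small_grid <- function(n = 10) {
  grid_field(seq(44.5, 45.5, length.out = n),
             seq(-74.5, -73.5, length.out = n),
             matrix(0, n, n), "O3", dx_km = 10)
}

test_that("station networks honour the land-use mix and the seed", {
  g <- small_grid()
  st <- make_station_network(g, 50, land_use_mix = c(rural = 1,
                                                     suburban = 0,
                                                     urban = 0), seed = 3)
  expect_true(all(st$land_use == "rural"))
  st2 <- make_station_network(g, 50, land_use_mix = c(rural = 1,
                                                      suburban = 0,
                                                      urban = 0), seed = 3)
  expect_identical(st, st2)
  expect_true(all(st$lat >= 44.5 & st$lat <= 45.5))
  # clustered placement shrinks the mean nearest-neighbour distance
  mean_nn <- function(s) {
    d <- distance_matrix_km(s$lat, s$lon); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn_u <- nn_c <- numeric(20)
  for (i in 1:20) {
    nn_u[i] <- mean_nn(make_station_network(g, 60, seed = i))
    nn_c[i] <- mean_nn(make_station_network(g, 60, clustered = TRUE,
                                            n_clusters = 4, seed = i))
  }
  expect_lt(mean(nn_c), mean(nn_u))
})

test_that("truth fields reproduce the requested mean, variance and correlation", {
  g <- small_grid(10)
  flat <- simulate_truth(g, mean = 40, variance = 0, lc_km = 60, seed = 1)
  expect_equal(flat$values, matrix(40, 10, 10))
  fields <- simulate_truth(g, mean = 40, variance = 25, lc_km = 60,
                           seed = 2, n_fields = 200)
  vals <- sapply(fields, function(f) as.vector(f$values))  # cells x draws
  cell_var <- apply(vals, 1, var)
  expect_lt(abs(mean(cell_var) - 25) / 25, 0.15)
  expect_lt(abs(mean(vals) - 40), 0.5)
  # empirical correlation tracks exp(-d/lc) for d up to 2*lc
  glat <- rep(g$lats, times = 10); glon <- rep(g$lons, each = 10)
  idx <- seq(1, 100, by = 7)
  emp <- cor(t(vals[idx, ]))
  dmat <- distance_matrix_km(glat[idx], glon[idx])
  sel <- upper.tri(dmat) & dmat <= 120
  expect_lt(max(abs(emp[sel] - exp(-dmat[sel] / 60))), 0.3)
  expect_lt(mean(abs(emp[sel] - exp(-dmat[sel] / 60))), 0.1)
})

test_that("forecasts carry the configured background error and regional offset", {
  g <- small_grid(10)
  truth <- simulate_truth(g, 40, 25, 60, seed = 5)
  # zero background error and no bias: forecast equals truth
  f0 <- simulate_forecast(truth, sigma_b2 = 0, lc_bg_km = 60, seed = 6)
  expect_equal(f0$values, truth$values)
  # ensemble background error variance matches sigma_b2
  truths <- rep(list(truth), 200)
  fs <- simulate_forecast(truths, sigma_b2 = 16, lc_bg_km = 60, seed = 7)
  errs <- sapply(seq_along(fs), function(i)
    as.vector(fs[[i]]$values - truth$values))
  expect_lt(abs(mean(apply(errs, 1, var)) - 16) / 16, 0.15)
  # constant in-region offset of -5 appears as +5 in truth - forecast
  reg <- bias_region("box", lat = c(44.6, 44.6, 45.4, 45.4),
                     lon = c(-74.4, -73.6, -73.6, -74.4))
  fb <- simulate_forecast(truth, sigma_b2 = 0, lc_bg_km = 60,
                          bias_regions = list(reg), bias_offsets = -5,
                          seed = 8)
  glat <- rep(g$lats, times = 10); glon <- rep(g$lons, each = 10)
  inside <- matrix(point_in_polygon(glat, glon, reg), 10, 10)
  expect_equal(mean(truth$values[inside] - fb$values[inside]), 5)
  expect_equal(mean(truth$values[!inside] - fb$values[!inside]), 0)
})

test_that("observation noise follows the land-use error model", {
  g <- small_grid(8)
  truth <- simulate_truth(g, 40, 0, 60, seed = 9)  # constant truth
  st <- station_set(data.frame(
    id = c("R", "S", "U"), lat = c(44.7, 45.0, 45.3),
    lon = c(-74.2, -74.0, -73.8),
    land_use = c("rural", "suburban", "urban")))
  # zero noise: observations equal the interpolated truth
  obs0 <- simulate_observations(truth, st, sigma_instr2 = 1e-18, seed = 10)
  expect_equal(obs0$value, rep(40, 3), tolerance = 1e-6)
  # 1000 hours: per-class empirical variance within 15% of the model
  truths <- rep(list(truth), 1000)
  obs <- simulate_observations(truths, st, sigma_instr2 = 4, seed = 11)
  v <- tapply(obs$value - 40, obs$station_id, var)
  expect_lt(abs(v[["R"]] - 8) / 8, 0.15)
  expect_lt(abs(v[["S"]] - 14) / 14, 0.15)
  expect_lt(abs(v[["U"]] - 24) / 24, 0.15)
  # urban noise exceeds rural for the same instrument
  expect_gt(v[["U"]], v[["R"]])
})

test_that("scenes are bit-reproducible under a fixed seed", {
  s1 <- simulate_scene(n_lat = 8, n_lon = 8, n_stations = 10, n_hours = 2,
                       seed = 12)
  s2 <- simulate_scene(n_lat = 8, n_lon = 8, n_stations = 10, n_hours = 2,
                       seed = 12)
  expect_identical(s1$obs, s2$obs)
  expect_identical(s1$forecasts[[2]]$values, s2$forecasts[[2]]$values)
  expect_identical(s1$stations, s2$stations)
})
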