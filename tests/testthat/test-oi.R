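make_innov <- function(stations, y_o, forecast = toy_grid()) {
  hxf <- interpolate_to_stations(forecast, stations)
  innovation_vector(stations, y_o, as.numeric(hxf), forecast$pollutant,
                    forecast$valid_time)
}

test_that("innovation matrix entries follow the exponential covariance", {
  # scalar case: diagonal is sigma_f^2 + sigma_o^2
  st1 <- station_set(data.frame(id = "A", lat = 45, lon = -74,
                                land_use = "rural"))
  stats1 <- error_stats("O3", sigma_b2 = 16, lc_km = 100,
                        sigma_o2_by_class = c(rural = 9))
  A1 <- build_innovation_matrix(make_innov(st1, 50), stats1)
  expect_equal(A1[1, 1], 25)

  # two stations 100 km apart, sigma_f = 4 both, Lc = 100 km
  lat2 <- 45 + 100 / (6371 * pi / 180)  # 100 km due north
  st2 <- station_set(data.frame(id = c("A", "B"), lat = c(45, lat2),
                                lon = -74, land_use = "rural"))
  A2 <- build_innovation_matrix(make_innov(st2, c(50, 50)), stats1)
  expect_equal(A2[1, 2], 16 * exp(-1), tolerance = 1e-9)
  expect_equal(A2[1, 2], A2[2, 1])

  # any valid configuration is symmetric positive definite
  st <- toy_stations(n = 12, seed = 3)
  A <- build_innovation_matrix(make_innov(st, rep(50, 12)), toy_stats())
  expect_equal(A, t(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("Cholesky solve matches an explicit matrix inverse", {
  st <- toy_stations(n = 5, seed = 9)
  stats <- toy_stats()
  innov <- make_innov(st, 50 + rnorm(5, 0, 4))
  A <- build_innovation_matrix(innov, stats)
  w <- solve_weights(A, innov$d)
  expect_equal(w, as.numeric(solve(A) %*% innov$d), tolerance = 1e-10)
  expect_lt(sqrt(sum((A %*% w - innov$d)^2)),
            1e-8 * sqrt(sum(innov$d^2)))
  expect_equal(solve_weights(A, rep(0, 5)), rep(0, 5))
})

test_that("decoupled stations reduce to scalar weights", {
  # far apart with a short correlation length: A is numerically diagonal
  st <- station_set(data.frame(id = c("A", "B"), lat = c(44, 46),
                               lon = c(-75, -73), land_use = "rural"))
  stats <- error_stats("O3", sigma_b2 = 16, lc_km = 5,
                       sigma_o2_by_class = c(rural = 9))
  innov <- make_innov(st, c(55, 47))
  A <- build_innovation_matrix(innov, stats)
  w <- solve_weights(A, innov$d)
  expect_equal(w, innov$d / 25, tolerance = 1e-6)
})

test_that("single-observation increment follows the scalar gain and decays", {
  g <- toy_grid(value = 50)
  # station exactly on a cell center
  st <- station_set(data.frame(id = "A", lat = g$lats[8], lon = g$lons[8],
                               land_use = "rural"))
  stats <- error_stats("O3", sigma_b2 = 16, lc_km = 60,
                       sigma_o2_by_class = c(rural = 9))
  obs <- data.frame(station_id = "A", value = 55)  # innovation = 5
  prod <- analyze(g, obs, st, stats)
  at_station <- prod$increment$values[8, 8]
  expect_equal(at_station, 5 * 16 / 25, tolerance = 1e-9)
  # decay: increment(d) / increment(0) = exp(-d / Lc) along the grid
  d_cells <- great_circle_km(g$lats[8], g$lons[8], g$lats[8], g$lons)
  expect_equal(prod$increment$values[8, ] / at_station,
               exp(-d_cells / 60), tolerance = 1e-9)
})

test_that("observation error limits recover the two gain extremes", {
  g <- toy_grid(value = 50)
  st <- station_set(data.frame(id = "A", lat = g$lats[8], lon = g$lons[8],
                               land_use = "rural"))
  obs <- data.frame(station_id = "A", value = 60)
  # sigma_o -> 0: analysis reproduces the observation at the station
  s0 <- error_stats("O3", sigma_b2 = 16, lc_km = 60,
                    sigma_o2_by_class = c(rural = 1e-10))
  p0 <- analyze(g, obs, st, s0)
  expect_equal(p0$analysis$values[8, 8], 60, tolerance = 1e-6)
  # sigma_o -> Inf: forecast unchanged
  sI <- error_stats("O3", sigma_b2 = 16, lc_km = 60,
                    sigma_o2_by_class = c(rural = 1e12))
  pI <- analyze(g, obs, st, sI)
  expect_equal(pI$analysis$values, g$values, tolerance = 1e-6)
})

test_that("analysis equals the dense-matrix oracle for 20 stations", {
  for (seed in c(1, 2)) {
    g <- toy_grid(value = 45)
    st <- toy_stations(n = 20, seed = seed)
    set.seed(seed + 100)
    y <- 45 + rnorm(20, 0, 4)
    stats <- toy_stats()
    prod <- analyze(g, data.frame(station_id = st$id, value = y), st, stats)
    inc_oracle <- oi_dense_oracle(g, st, y, stats)
    expect_equal(prod$increment$values, inc_oracle, tolerance = 1e-10)
    expect_equal(prod$analysis$values, g$values + inc_oracle,
                 tolerance = 1e-10)
  }
})

test_that("the analysis is invariant to observation ordering", {
  g <- toy_grid(value = 45)
  st <- toy_stations(n = 10, seed = 5)
  set.seed(500)
  y <- 45 + rnorm(10, 0, 4)
  stats <- toy_stats()
  p1 <- analyze(g, data.frame(station_id = st$id, value = y), st, stats)
  perm <- sample(10)
  p2 <- analyze(g, data.frame(station_id = st$id[perm], value = y[perm]),
                st[perm, ], stats)
  expect_equal(p1$analysis$values, p2$analysis$values, tolerance = 1e-12)
})

test_that("co-located stations are merged before the matrix build", {
  g <- toy_grid(value = 50)
  st <- station_set(data.frame(id = c("A", "B", "C"),
                               lat = c(45, 45.0001, 45.5),
                               lon = c(-74, -74, -73.5),
                               land_use = "rural"))
  stats <- error_stats("O3", sigma_b2 = 16, lc_km = 60,
                       sigma_o2_by_class = c(rural = 9))
  obs <- data.frame(station_id = c("A", "B", "C"), value = c(54, 56, 50))
  prod <- analyze(g, obs, st, stats)   # must not fail on near-singular A
  expect_length(prod$innovations, 2L)  # A and B averaged
  expect_true(any(grepl("\\+", prod$innovations$stations$id)))
})

test_that("rejecting every observation returns the forecast with a warning", {
  g <- toy_grid(value = 50)
  st <- toy_stations(n = 4)
  obs <- data.frame(station_id = st$id, value = rep(-10, 4))  # all < 0
  expect_warning(
    prod <- analyze(g, obs, st, toy_stats(), qc_config = qc_config()),
    "no observations accepted")
  expect_equal(prod$analysis$values, g$values)
  expect_identical(unname(prod$qc_counts["accepted"]), 0L)
  expect_identical(unname(prod$qc_counts["RANGE"]), 4L)
})

test_that("assimilation moves the analysis toward a known truth", {
  scene <- simulate_scene(n_lat = 20, n_lon = 20, n_stations = 120,
                          n_hours = 1, truth_var = 100, truth_lc_km = 150,
                          sigma_b2 = 25, lc_bg_km = 60, sigma_instr2 = 4,
                          seed = 31)
  stats <- error_stats("O3", sigma_b2 = 25, lc_km = 60,
                       sigma_o2_by_class = c(
                         rural = obs_error_s14(4, 10, "rural"),
                         suburban = obs_error_s14(4, 10, "suburban"),
                         urban = obs_error_s14(4, 10, "urban")))
  obs1 <- scene$obs[scene$obs$time == 1, ]
  prod <- analyze(scene$forecasts[[1]], obs1, scene$stations, stats)
  err_fc <- scene$forecasts[[1]]$values - scene$truths[[1]]$values
  err_an <- prod$analysis$values - scene$truths[[1]]$values
  expect_lt(sd(err_an), sd(err_fc))
})
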