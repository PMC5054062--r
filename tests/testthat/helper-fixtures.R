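# small reusable fixtures built in code

# regular grid over a ~200 x 230 km box, constant background value
toy_grid <- function(value = 50, n = 15, pollutant = "O3") {
  grid_field(seq(44, 46, length.out = n),
             seq(-75, -73, length.out = n),
             matrix(value, n, n), pollutant, valid_time = 0L, dx_km = 10)
}

toy_stations <- function(n = 8, seed = 42) {
  set.seed(seed)
  station_set(data.frame(
    id = sprintf("A%02d", seq_len(n)),
    lat = runif(n, 44.2, 45.8),
    lon = runif(n, -74.8, -73.2),
    land_use = sample(c("rural", "suburban", "urban"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

toy_stats <- function(sigma_b2 = 16, lc_km = 60) {
  error_stats("O3", sigma_b2 = sigma_b2, lc_km = lc_km,
              sigma_o2_by_class = c(rural = 8, suburban = 14, urban = 24))
}

# dense-matrix optimal interpolation oracle: x^a = x^f + (HB)^T A^-1 d,
# every covariance written out explicitly and solved with solve()
oi_dense_oracle <- function(forecast, stations, y_o, stats) {
  hxf <- interpolate_to_stations(forecast, stations)
  d <- y_o - hxf
  sf_k <- rep(sqrt(stats$sigma_b2), nrow(stations))
  so2 <- stats$sigma_o2_by_class[stations$land_use]
  dm <- distance_matrix_km(stations$lat, stations$lon)
  A <- outer(sf_k, sf_k) * exp(-dm / stats$lc_km)
  diag(A) <- sf_k^2 + so2
  nlat <- length(forecast$lats); nlon <- length(forecast$lons)
  glat <- rep(forecast$lats, times = nlon)
  glon <- rep(forecast$lons, each = nlat)
  HB <- sapply(seq_len(nrow(stations)), function(k)
    sqrt(stats$sigma_b2) * sf_k[k] *
      exp(-great_circle_km(glat, glon, stations$lat[k], stations$lon[k]) /
            stats$lc_km))
  matrix(HB %*% solve(A, d), nlat, nlon)
}
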