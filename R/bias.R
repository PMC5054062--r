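#' Bias-correction region
#'
#' A closed lat/lon polygon inside which a spatially averaged forecast
#' bias correction applies; outside, the correction decays exponentially
#' with distance to the boundary so the corrected field stays continuous.
#'
#' @param name Region label.
#' @param lat,lon Polygon vertex coordinates (closed implicitly; do not
#'   repeat the first vertex).
#' @param decay_km e-folding distance of the correction outside the
#'   boundary (default 100 km).
#' @param min_stations Minimum QC-accepted in-region stations required to
#'   estimate a bias (default 5).
#' @return Object of class `bias_region`.
#' @export
bias_region <- function(name, lat, lon, decay_km = 100, min_stations = 5) {
  stopifnot(length(lat) == length(lon), length(lat) >= 3, decay_km > 0)
  structure(list(name = name, lat = as.numeric(lat), lon = as.numeric(lon),
                 decay_km = decay_km, min_stations = min_stations),
            class = "bias_region")
}

#' Even-odd rule point-in-polygon test
#'
#' @param plat,plon Point coordinates (vectors).
#' @param region A [bias_region] (or any list with `lat`/`lon` vertex
#'   vectors describing a closed polygon).
#' @return Logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(plat, plon, region) {
  vy <- region$lat; vx <- region$lon
  nv <- length(vy)
  inside <- rep(FALSE, length(plat))
  j <- nv
  for (i in seq_len(nv)) {
    cross <- ((vy[i] > plat) != (vy[j] > plat)) &
      (plon < (vx[j] - vx[i]) * (plat - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# sample polygon edges at <= step_km resolution (in km along the edge)
polygon_boundary_points <- function(region, step_km = 5) {
  nv <- length(region$lat)
  lat <- numeric(0); lon <- numeric(0)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    seg <- great_circle_km(region$lat[i], region$lon[i],
                           region$lat[j], region$lon[j])
    k <- max(1L, ceiling(seg / step_km))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    lat <- c(lat, region$lat[i] + t * (region$lat[j] - region$lat[i]))
    lon <- c(lon, region$lon[i] + t * (region$lon[j] - region$lon[i]))
  }
  list(lat = lat, lon = lon)
}

#' Estimate the regional mean forecast bias
#'
#' Mean innovation (observation minus forecast) over the QC-accepted
#' stations inside the region.  With fewer than `min_stations` in-region
#' stations no correction is estimated (`NA` with a warning).
#'
#' @param innov An [innovation_vector] of QC-accepted records.
#' @param region A [bias_region].
#' @return The mean bias (to be *added* to the forecast), or `NA`.
#' @export
estimate_regional_bias <- function(innov, region) {
  st <- innov$stations
  inside <- point_in_polygon(st$lat, st$lon, region)
  if (sum(inside) < region$min_stations) {
    warning("region '", region$name, "': only ", sum(inside),
            " station(s) inside; no bias correction")
    return(NA_real_)
  }
  mean(innov$d[inside])
}

#' Apply regional bias corrections to a forecast field
#'
#' Adds the estimated bias `b` inside each region and
#' `b * exp(-d_boundary / decay_km)` outside, where `d_boundary` is the
#' great-circle distance to the nearest sampled boundary point.  Where
#' regions overlap or compete, the nearest region's correction wins (no
#' double-adding).  Regions with `NA` bias are skipped.
#'
#' @param forecast A [grid_field].
#' @param regions List of [bias_region] objects.
#' @param biases Numeric vector of biases aligned with `regions` (from
#'   [estimate_regional_bias]).
#' @param step_km Boundary sampling resolution (default 5 km).
#' @return The corrected [grid_field].
#' @export
apply_bias_field <- function(forecast, regions, biases, step_km = 5) {
  stopifnot(inherits(forecast, "grid_field"),
            length(regions) == length(biases))
  ok <- which(is.finite(biases) & biases != 0)
  if (!length(ok)) return(forecast)
  nlat <- length(forecast$lats); nlon <- length(forecast$lons)
  glat <- rep(forecast$lats, times = nlon)
  glon <- rep(forecast$lons, each = nlat)
  # per-cell distance to each region (0 inside) and its correction
  dist_to <- matrix(Inf, length(glat), length(ok))
  corr_of <- matrix(0, length(glat), length(ok))
  for (m in seq_along(ok)) {
    r <- regions[[ok[m]]]
    b <- biases[ok[m]]
    inside <- point_in_polygon(glat, glon, r)
    bp <- polygon_boundary_points(r, step_km)
    dmin <- rep(Inf, length(glat))
    out_idx <- which(!inside)
    if (length(out_idx)) {
      db <- distance_matrix_km(glat[out_idx], glon[out_idx], bp$lat, bp$lon)
      dmin[out_idx] <- apply(db, 1, min)
    }
    dmin[inside] <- 0
    dist_to[, m] <- dmin
    corr_of[, m] <- b * exp(-dmin / r$decay_km)
  }
  nearest <- max.col(-dist_to, ties.method = "first")
  corr <- corr_of[cbind(seq_along(glat), nearest)]
  out <- forecast
  out$values <- forecast$values + matrix(corr, nlat, nlon)
  out
}
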