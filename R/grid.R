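#' Gridded concentration field
#'
#' A `grid_field` is a regular latitude/longitude raster of one pollutant at
#' one valid hour: cell-center coordinates, a value matrix, the pollutant
#' name, and the nominal model resolution `dx_km` used by the
#' representativeness-error model.
#'
#' @param lats Numeric vector of cell-center latitudes, strictly increasing.
#' @param lons Numeric vector of cell-center longitudes, strictly increasing,
#'   in \[-180, 180\].
#' @param values Numeric matrix of dimension `length(lats) x length(lons)`
#'   (rows index latitude). `NA` marks missing cells.
#' @param pollutant One of `"O3"`, `"NO2"`, `"PM2.5"`, `"PM10"`, `"AQHI"`.
#' @param valid_time Valid hour (UTC), any scalar time stamp or integer hour.
#' @param dx_km Nominal grid resolution in km; must be positive.
#' @param units Concentration units; defaults to the conventional unit for
#'   the pollutant (ppbv for gases, ug/m3 for particulate matter, unitless
#'   for AQHI).
#'
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(lats, lons, values, pollutant,
                       valid_time = 0L, dx_km = 10, units = NULL) {
  pollutant <- match.arg(pollutant, c("O3", "NO2", "PM2.5", "PM10", "AQHI"))
  lats <- as.numeric(lats); lons <- as.numeric(lons)
  if (length(lats) < 2L || any(diff(lats) <= 0))
    stop("'lats' must be strictly increasing with length >= 2")
  if (length(lons) < 2L || any(diff(lons) <= 0))
    stop("'lons' must be strictly increasing with length >= 2")
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(lats), length(lons))))
    stop("'values' must be a ", length(lats), " x ", length(lons), " matrix")
  if (any(is.infinite(values)))
    stop("grid values must be finite or NA")
  if (!is.numeric(dx_km) || length(dx_km) != 1L || dx_km <= 0)
    stop("'dx_km' must be a positive scalar")
  if (is.null(units)) units <- default_units(pollutant)
  structure(list(lats = lats, lons = lons, values = values,
                 pollutant = pollutant, valid_time = valid_time,
                 dx_km = dx_km, units = units),
            class = "grid_field")
}

default_units <- function(pollutant) {
  switch(pollutant,
         O3 = "ppbv", NO2 = "ppbv",
         "PM2.5" = "ug/m3", PM10 = "ug/m3",
         AQHI = "1")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s], %d x %d cells, dx = %g km\n",
              x$pollutant, x$units, length(x$lats), length(x$lons), x$dx_km))
  cat(sprintf("  lat %g..%g, lon %g..%g, valid_time %s\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons),
              format(x$valid_time)))
  invisible(x)
}

#' @export
dim.grid_field <- function(x) dim(x$values)

same_grid <- function(a, b, tol = 1e-9) {
  length(a$lats) == length(b$lats) && length(a$lons) == length(b$lons) &&
    max(abs(a$lats - b$lats)) < tol && max(abs(a$lons - b$lons)) < tol
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371 km.  All arguments recycle;
#' `lat1`/`lon1` may be vectors against scalar `lat2`/`lon2` and vice versa.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90, abs(lat2) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(abs(lon1) > 180, abs(lon2) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  r <- 6371
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Pairwise great-circle distance matrix
#'
#' @param lat,lon Coordinate vectors of equal length.
#' @param lat2,lon2 Optional second set; if omitted the matrix is square and
#'   symmetric over the first set.
#' @return Matrix of distances in km, `length(lat) x length(lat2)`.
#' @export
distance_matrix_km <- function(lat, lon, lat2 = lat, lon2 = lon) {
  n <- length(lat); m <- length(lat2)
  outer(seq_len(n), seq_len(m), function(i, j)
    great_circle_km(lat[i], lon[i], lat2[j], lon2[j]))
}

#' Bilinear interpolation of a grid field to station locations
#'
#' Interpolates in latitude/longitude space from the four surrounding cell
#' centers.  Stations outside the grid's cell-center hull are not
#' extrapolated: their value is `NA` and they are listed in the
#' `"outside"` attribute so callers can drop them with a reason.
#'
#' @param field A [grid_field].
#' @param stations Data frame with columns `lat` and `lon` (and usually
#'   `id`).
#' @return Numeric vector of interpolated values, one per station, with an
#'   `"outside"` attribute giving the row indices of stations outside the
#'   grid.
#' @export
interpolate_to_stations <- function(field, stations) {
  stopifnot(inherits(field, "grid_field"))
  lat <- stations$lat; lon <- stations$lon
  inside <- lat >= min(field$lats) & lat <= max(field$lats) &
    lon >= min(field$lons) & lon <= max(field$lons)
  out <- rep(NA_real_, length(lat))
  if (any(inside)) {
    out[inside] <- pracma::interp2(field$lons, field$lats, field$values,
                                   lon[inside], lat[inside],
                                   method = "linear")
  }
  attr(out, "outside") <- which(!inside)
  out
}
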