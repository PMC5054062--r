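#' Monitoring station table
#'
#' Validates and normalizes a data frame of monitoring sites.  Stations
#' carry a land-use class (rural/suburban/urban) that drives the
#' representativeness part of the observation error, and optionally a
#' country label used by the verification-region partition.
#'
#' @param df Data frame with columns `id`, `lat`, `lon`, `land_use` and
#'   optionally `country` and `region`.
#' @return The validated data frame with class `station_set` prepended.
#' @export
station_set <- function(df) {
  req <- c("id", "lat", "lon", "land_use")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing station columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("station ids must be unique")
  if (any(abs(df$lat) > 90)) stop("station latitude outside [-90, 90]")
  if (any(abs(df$lon) > 180)) stop("station longitude outside [-180, 180]")
  bad <- setdiff(unique(df$land_use), c("rural", "suburban", "urban"))
  if (length(bad)) stop("unknown land_use class: ", paste(bad, collapse = ", "))
  class(df) <- unique(c("station_set", class(df)))
  df
}

#' Innovation vector
#'
#' Pairs QC-accepted observations with the forecast interpolated to the
#' stations; `d = y_o - h_xf` is the innovation (observation minus
#' prediction, OmP) the analysis assimilates.
#'
#' @param stations Station data frame (rows aligned with `y_o`).
#' @param y_o Observed concentrations.
#' @param h_xf Forecast interpolated to the stations.
#' @param pollutant,valid_time Metadata carried through to the product.
#' @return Object of class `innovation_vector` with elements `stations`,
#'   `y_o`, `h_xf`, `d`.
#' @export
innovation_vector <- function(stations, y_o, h_xf, pollutant, valid_time = 0L) {
  if (nrow(stations) != length(y_o) || length(y_o) != length(h_xf))
    stop("stations, y_o and h_xf must have matching length")
  if (length(y_o) && (any(!is.finite(y_o)) || any(!is.finite(h_xf))))
    stop("innovation inputs must be finite")
  structure(list(stations = stations, y_o = as.numeric(y_o),
                 h_xf = as.numeric(h_xf), d = as.numeric(y_o - h_xf),
                 pollutant = pollutant, valid_time = valid_time),
            class = "innovation_vector")
}

#' @export
length.innovation_vector <- function(x) length(x$d)

#' Merge co-located stations into pseudo-stations
#'
#' Stations closer than `min_sep_km` carry essentially the same spatial
#' information and make the innovation matrix ill-conditioned; their
#' observations (and forecast equivalents) are averaged into one
#' pseudo-station located at the group centroid before the matrix is built.
#'
#' @param innov An [innovation_vector].
#' @param min_sep_km Merge radius in km (default 1).
#' @return An [innovation_vector] with co-located stations merged.
#' @export
merge_colocated <- function(innov, min_sep_km = 1) {
  n <- length(innov)
  if (n < 2L) return(innov)
  st <- innov$stations
  dmat <- distance_matrix_km(st$lat, st$lon)
  grp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (dmat[i, j] < min_sep_km) grp[grp == grp[j]] <- grp[i]
  }
  if (length(unique(grp)) == n) return(innov)
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  keep <- !duplicated(grp)
  st2 <- st[keep, , drop = FALSE]
  st2$lat <- agg(st$lat); st2$lon <- agg(st$lon)
  st2$id <- as.character(tapply(st$id, grp, function(s)
    paste(sort(s), collapse = "+")))
  innovation_vector(st2, agg(innov$y_o), agg(innov$h_xf),
                    innov$pollutant, innov$valid_time)
}
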