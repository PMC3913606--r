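#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km.  Inputs are
#' signed decimal degrees (south and west negative) and are recycled, so the
#' function can compute point-to-point, point-to-track or pairwise distances.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees WGS84.
#' @param lat2,lon2 coordinates of the second point(s).
#' @return numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0)      # one degree of latitude, ~111.19 km
#' haversine_km(-48.4, 68.4, -48.4, 69.4)
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90, na.rm = TRUE))
  r <- 6371.0
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  # clamp against rounding just above 1 for antipodal-ish inputs
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Convert local east/north offsets (km) from an origin to lat/lon degrees.
#'
#' Equirectangular local tangent-plane conversion, adequate for the
#' few-hundred-km scales of foraging trips.  Used by the track simulator.
#'
#' @param x_km,y_km east and north offsets from the origin, km.
#' @param origin c(lat, lon) in decimal degrees.
#' @return data.frame with columns `lat`, `lon`.
#' @keywords internal
local_to_lonlat <- function(x_km, y_km, origin) {
  km_per_deg <- 6371.0 * pi / 180
  lat <- origin[[1]] + y_km / km_per_deg
  lon <- origin[[2]] + x_km / (km_per_deg * cos(origin[[1]] * pi / 180))
  data.frame(lat = lat, lon = lon)
}

#' @rdname local_to_lonlat
#' @param lat,lon coordinates to project.
#' @keywords internal
lonlat_to_local <- function(lat, lon, origin) {
  km_per_deg <- 6371.0 * pi / 180
  data.frame(
    x_km = (lon - origin[[2]]) * km_per_deg * cos(origin[[1]] * pi / 180),
    y_km = (lat - origin[[1]]) * km_per_deg
  )
}
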