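# Geodesic primitives on a sphere of radius 6,371,000 m (WGS84 coordinates,
# haversine distances). At stop scale (tens of metres to a few km) the
# sub-0.5% sphere-vs-ellipsoid error is immaterial.

EARTH_RADIUS_M <- 6371000

#' Great-circle (haversine) distance
#'
#' Distance in metres between points given as WGS84 decimal-degree
#' latitude/longitude, on a sphere of radius 6,371,000 m. Vectorised and
#' recycled like the usual arithmetic operators.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in metres.
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of longitude at the equator, ~111 km
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90, na.rm = TRUE))
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Initial bearing between two points
#'
#' Forward azimuth in degrees, [0, 360), from point 1 to point 2.
#'
#' @inheritParams haversine_m
#' @return Bearing(s) in degrees.
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Circular difference between two headings
#'
#' Absolute angular difference in degrees, in [0, 180]; 359 vs 1 gives 2,
#' not 358.
#'
#' @param h1,h2 Headings in degrees.
#' @return Absolute circular difference in degrees.
#' @export
heading_diff_deg <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

#' Destination point given start, bearing and distance
#'
#' Used by the trajectory generator to lay out places and travel legs.
#'
#' @param lat,lon Start coordinates, decimal degrees.
#' @param bearing Bearing in degrees.
#' @param dist_m Distance in metres.
#' @return A list with `lat` and `lon` vectors.
#' @export
dest_point <- function(lat, lon, bearing, dist_m) {
  p1 <- lat * pi / 180
  l1 <- lon * pi / 180
  th <- bearing * pi / 180
  dr <- dist_m / EARTH_RADIUS_M
  p2 <- asin(sin(p1) * cos(dr) + cos(p1) * sin(dr) * cos(th))
  l2 <- l1 + atan2(
    sin(th) * sin(dr) * cos(p1),
    cos(dr) - sin(p1) * sin(p2)
  )
  list(lat = p2 * 180 / pi, lon = ((l2 * 180 / pi + 540) %% 360) - 180)
}

MPH_PER_MPS <- 3600 / 1609.34

#' Speed implied by two timestamped fixes
#'
#' Haversine displacement divided by elapsed time, in miles per hour. Used by
#' the anomaly screen when the device's recorded speed column is absent.
#'
#' @param lat1,lon1,t1 First fix: coordinates and time (POSIXct or seconds).
#' @param lat2,lon2,t2 Second fix; `t2` must be strictly later than `t1`.
#' @return Implied speed(s) in mph.
#' @export
implied_speed_mph <- function(lat1, lon1, t1, lat2, lon2, t2) {
  dt <- as.numeric(t2) - as.numeric(t1)
  if (any(dt <= 0)) {
    abort("implied_speed_mph(): t2 must be strictly later than t1")
  }
  haversine_m(lat1, lon1, lat2, lon2) / dt * MPH_PER_MPS
}
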