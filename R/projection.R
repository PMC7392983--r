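# Per-city azimuthal equidistant (AEQD) projection on a sphere of radius
# 6378137 m, centred on the city centroid. AEQD preserves distances from the
# centre exactly and is adequate at city scale (boundaries limited to
# 1000 km); the forward and inverse maps are exact inverses, so lon/lat
# round-trips are limited only by floating point.

EARTH_RADIUS_M <- 6378137

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Forward azimuthal equidistant projection
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0,lat0 projection centre in degrees.
#' @param radius sphere radius in meters.
#' @return list with numeric vectors `x`, `y` in meters.
#' @export
aeqd_forward <- function(lon, lat, lon0, lat0, radius = EARTH_RADIUS_M) {
  lam <- .deg2rad(lon); phi <- .deg2rad(lat)
  lam0 <- .deg2rad(lon0); phi0 <- .deg2rad(lat0)
  dlam <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  list(x = radius * k * cos(phi) * sin(dlam),
       y = radius * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam)))
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y projected coordinates in meters.
#' @param lon0,lat0 projection centre in degrees.
#' @param radius sphere radius in meters.
#' @return list with numeric vectors `lon`, `lat` in degrees.
#' @export
aeqd_inverse <- function(x, y, lon0, lat0, radius = EARTH_RADIUS_M) {
  lam0 <- .deg2rad(lon0); phi0 <- .deg2rad(lat0)
  rho <- sqrt(x * x + y * y)
  c_ang <- rho / radius
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(pmin(1, pmax(-1, cosc * sin(phi0) + y * sinc * cos(phi0) / rho))))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc, rho * cosc * cos(phi0) - y * sinc * sin(phi0)))
  list(lon = .rad2deg(lam), lat = .rad2deg(phi))
}

.project_geom <- function(geom, lon0, lat0) {
  lapply(geom, function(poly) lapply(poly, function(ring) {
    p <- aeqd_forward(ring[, 1L], ring[, 2L], lon0, lat0)
    cbind(p$x, p$y)
  }))
}

.project_segments <- function(segs, lon0, lat0) {
  lapply(segs, function(m) {
    p <- aeqd_forward(m[, 1L], m[, 2L], lon0, lat0)
    cbind(p$x, p$y)
  })
}

#' Project a city boundary and road network to planar meters
#'
#' Both inputs must be in geographic longitude/latitude (degrees). The
#' output shares one planar frame: an azimuthal equidistant projection
#' centred on the boundary's area centroid, so the centroid maps to (0, 0).
#'
#' @param boundary_geographic list with `city_id`, `country`, and `geom`
#'   (list of polygons, each a list of lon/lat rings), e.g. from
#'   [read_boundaries_geojson()].
#' @param roads_geographic list of lon/lat polyline matrices (or a list with
#'   a `segments` element), e.g. from [read_roads_geojson()]. May be `NULL`.
#' @param units_geographic optional list of subcity units, each with
#'   `subcity_id`, `area_km2`, and a lon/lat `geom`; projected in the same
#'   frame.
#' @return list with `boundary` (a `city_boundary`), `roads`
#'   (a `road_network`), and `units` (projected unit list or `NULL`).
#' @export
project_city <- function(boundary_geographic, roads_geographic = NULL,
                         units_geographic = NULL) {
  geom <- boundary_geographic$geom
  if (is.null(geom) || length(geom) == 0L) {
    stop("empty boundary geometry", call. = FALSE)
  }
  bb <- geom_bbox(geom)
  # refuse inputs whose extent would distort badly under one local projection
  span_m <- max(abs(bb[3L] - bb[1L]) * cos(.deg2rad(mean(c(bb[2L], bb[4L])))),
                abs(bb[4L] - bb[2L])) * pi / 180 * EARTH_RADIUS_M
  if (span_m > 1000e3) {
    stop("geometry spans more than 1000 km; refusing single-city projection",
         call. = FALSE)
  }
  ctr <- geom_centroid(geom)
  lon0 <- ctr[1L]; lat0 <- ctr[2L]
  crs <- list(type = "aeqd_sphere", lon0 = lon0, lat0 = lat0,
              radius_m = EARTH_RADIUS_M)

  pgeom <- .project_geom(geom, lon0, lat0)
  validate_geom(pgeom)
  boundary <- structure(
    list(city_id = boundary_geographic$city_id,
         country = boundary_geographic$country,
         geom = pgeom, crs = crs),
    class = "city_boundary")

  segs <- NULL
  if (!is.null(roads_geographic)) {
    segs <- if (!is.null(roads_geographic$segments)) roads_geographic$segments
            else roads_geographic
  }
  roads <- structure(
    list(segments = if (is.null(segs)) list()
         else .project_segments(segs, lon0, lat0),
         crs = crs),
    class = "road_network")

  units <- NULL
  if (!is.null(units_geographic)) {
    units <- lapply(units_geographic, function(u) {
      u$geom <- .project_geom(u$geom, lon0, lat0)
      u
    })
  }
  list(boundary = boundary, roads = roads, units = units)
}

#' @exportS3Method base::print
print.city_boundary <- function(x, ...) {
  bb <- geom_bbox(x$geom)
  cat(sprintf("<city_boundary> %s (%s): area %.2f km2, bbox %.0f x %.0f m\n",
              x$city_id, x$country, geom_area(x$geom) / 1e6,
              bb[3L] - bb[1L], bb[4L] - bb[2L]))
  invisible(x)
}

#' @exportS3Method base::print
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d polylines, total length %.1f km\n",
              length(x$segments), edges_length(road_edges(x)) / 1e3))
  invisible(x)
}
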