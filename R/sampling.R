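# Point-lattice sampling over city polygons, buffer road-length computation,
# eligibility filtering, and spatial assignment to subcity units.

#' Generate a regular point lattice over a city boundary
#'
#' Points are placed on an axis-aligned lattice with the given spacing,
#' anchored at the lower-left corner of the boundary's bounding box, and
#' kept if they fall inside the polygon (boundary inclusive). Output order
#' is row-major (y ascending, then x ascending) and fully deterministic.
#'
#' @param boundary a `city_boundary` from [project_city()] (planar meters).
#' @param spacing_m lattice spacing in meters (default 500, the audit's
#'   sampling interval).
#' @return data.frame with columns point_id, city_id, x, y.
#' @export
generate_point_grid <- function(boundary, spacing_m = 500) {
  stopifnot(inherits(boundary, "city_boundary"))
  if (!is.numeric(spacing_m) || length(spacing_m) != 1L || spacing_m <= 0) {
    stop("spacing_m must be a single positive number", call. = FALSE)
  }
  empty <- data.frame(point_id = character(0), city_id = character(0),
                      x = numeric(0), y = numeric(0),
                      stringsAsFactors = FALSE)
  if (geom_area(boundary$geom) <= 0) {
    warning("zero-area boundary: returning no sample points")
    return(empty)
  }
  bb <- geom_bbox(boundary$geom)
  # small epsilon so lattice points landing exactly on the upper bbox edge
  # survive floating-point seq() truncation
  eps <- spacing_m * 1e-9
  xs <- seq(bb[1L], bb[3L] + eps, by = spacing_m)
  ys <- seq(bb[2L], bb[4L] + eps, by = spacing_m)
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE) # row-major in y
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    point_in_geom(grid$x[i], grid$y[i], boundary$geom)
  }, logical(1))
  pts <- grid[keep, , drop = FALSE]
  if (nrow(pts) == 0L) {
    warning("no lattice points fall inside the boundary")
    return(empty)
  }
  data.frame(
    point_id = sprintf("%s_%06d", boundary$city_id, seq_len(nrow(pts))),
    city_id = boundary$city_id,
    x = pts$x, y = pts$y,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Road length within a buffer around each point
#'
#' Clips every road polyline exactly to the closed disc of radius
#' `radius_m` around each point and sums the clipped lengths.
#'
#' @param points data.frame with columns x, y (or a single point as a
#'   length-2 numeric vector).
#' @param roads a `road_network` (or list of polyline matrices).
#' @param radius_m buffer radius in meters (> 0; default 100).
#' @return numeric vector of road lengths in meters, one per point.
#' @export
road_length_within <- function(points, roads, radius_m = 100) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    stop("radius_m must be a single positive number", call. = FALSE)
  }
  if (is.numeric(points) && length(points) == 2L) {
    points <- data.frame(x = points[1L], y = points[2L])
  }
  edges <- road_edges(roads)
  vapply(seq_len(nrow(points)), function(i) {
    clip_edges_to_disc(edges, points$x[i], points$y[i], radius_m)
  }, numeric(1))
}

#' Keep only points with road within the buffer
#'
#' @param points data.frame with a `road_length_m` column.
#' @return the rows with `road_length_m > 0`, order preserved. Idempotent.
#' @export
filter_eligible <- function(points) {
  if (is.null(points$road_length_m)) {
    stop("road_length_m must be computed before eligibility filtering",
         call. = FALSE)
  }
  points[points$road_length_m > 0, , drop = FALSE]
}

#' Assign sample points to subcity units
#'
#' Each point gets the `subcity_id` of the unit polygon containing it
#' (boundary inclusive). A point on a shared boundary goes to the unit with
#' the lexicographically smallest id; a point inside no unit gets `NA`.
#' Units whose interiors overlap are a data error and are rejected.
#'
#' @param points data.frame with columns x, y.
#' @param units list of units, each a list with `subcity_id` and planar
#'   `geom`.
#' @return `points` with a `subcity_id` column added/overwritten.
#' @export
assign_subcity <- function(points, units) {
  if (length(units) == 0L) {
    points$subcity_id <- rep(NA_character_, nrow(points))
    return(points)
  }
  ids <- vapply(units, function(u) u$subcity_id, character(1))
  ord <- order(ids) # lexicographic tie-break: test smallest ids first
  assigned <- rep(NA_character_, nrow(points))
  interior_hits <- integer(nrow(points))
  for (k in ord) {
    u <- units[[k]]
    for (i in seq_len(nrow(points))) {
      inside <- point_in_geom(points$x[i], points$y[i], u$geom)
      if (inside) {
        if (is.na(assigned[i])) assigned[i] <- u$subcity_id
        if (point_in_geom_interior(points$x[i], points$y[i], u$geom)) {
          interior_hits[i] <- interior_hits[i] + 1L
        }
      }
    }
  }
  if (any(interior_hits > 1L)) {
    stop("overlapping subcity unit interiors detected", call. = FALSE)
  }
  points$subcity_id <- assigned
  points
}

#' Build the eligible sample frame for one city
#'
#' Convenience wrapper: lattice generation, buffer road lengths,
#' eligibility flag, and subcity assignment in one pass.
#'
#' @param boundary a `city_boundary`.
#' @param roads a `road_network`.
#' @param units optional projected subcity unit list.
#' @param spacing_m lattice spacing (default 500 m).
#' @param radius_m buffer radius (default 100 m).
#' @return data.frame: point_id, city_id, subcity_id, x, y, lon, lat,
#'   road_length_m, eligible.
#' @export
build_sample_frame <- function(boundary, roads, units = NULL,
                               spacing_m = 500, radius_m = 100) {
  pts <- generate_point_grid(boundary, spacing_m)
  if (nrow(pts) == 0L) {
    pts$subcity_id <- character(0)
    pts$lon <- numeric(0); pts$lat <- numeric(0)
    pts$road_length_m <- numeric(0); pts$eligible <- logical(0)
    return(pts)
  }
  pts$road_length_m <- road_length_within(pts, roads, radius_m)
  pts$eligible <- pts$road_length_m > 0
  if (!is.null(units)) {
    pts <- assign_subcity(pts, units)
  } else {
    pts$subcity_id <- NA_character_
  }
  if (!is.null(boundary$crs) && identical(boundary$crs$type, "aeqd_sphere")) {
    ll <- aeqd_inverse(pts$x, pts$y, boundary$crs$lon0, boundary$crs$lat0,
                       boundary$crs$radius_m)
    pts$lon <- ll$lon; pts$lat <- ll$lat
  } else {
    pts$lon <- NA_real_; pts$lat <- NA_real_
  }
  pts[, c("point_id", "city_id", "subcity_id", "x", "y", "lon", "lat",
          "road_length_m", "eligible")]
}
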