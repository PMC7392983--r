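# Planar geometry primitives: ring areas, point-in-polygon with a
# boundary-inclusive contract, and exact clipping of polylines to a closed
# disc. Geometries are stored as plain matrices so every operation is
# auditable against brute-force oracles.
#
# Conventions:
#   * a ring is an n x 2 matrix of vertices; the closing vertex may be
#     repeated or not (it is normalised away on construction)
#   * a polygon is a list of rings: rings[[1]] is the exterior, any further
#     rings are holes
#   * a geometry ("geom") is a list of polygons (MultiPolygon semantics)
#   * a road network segment is an n x 2 matrix (a polyline with >= 2 vertices)

#' Normalise a polygon ring
#'
#' Drops a repeated closing vertex and validates shape.
#' @param ring numeric matrix with two columns (x, y).
#' @return matrix with no repeated closing vertex.
#' @keywords internal
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L || nrow(ring) < 3L) {
    stop("a polygon ring needs a numeric n x 2 matrix with >= 3 vertices",
         call. = FALSE)
  }
  n <- nrow(ring)
  if (isTRUE(all.equal(ring[1L, ], ring[n, ], check.attributes = FALSE))) {
    ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(ring) < 3L) {
    stop("degenerate polygon ring (< 3 distinct vertices)", call. = FALSE)
  }
  if (any(!is.finite(ring))) stop("non-finite ring coordinates", call. = FALSE)
  unname(ring)
}

#' Signed area of a ring (shoelace formula)
#' @param ring n x 2 matrix, not necessarily closed.
#' @return signed area; positive for counter-clockwise orientation.
#' @keywords internal
ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Total area of a geometry (exterior rings minus holes)
#' @param geom list of polygons, each a list of rings.
#' @keywords internal
geom_area <- function(geom) {
  sum(vapply(geom, function(poly) {
    a <- abs(ring_area_signed(poly[[1L]]))
    if (length(poly) > 1L) {
      a <- a - sum(vapply(poly[-1L], function(r) abs(ring_area_signed(r)),
                          numeric(1)))
    }
    a
  }, numeric(1)))
}

#' Area-weighted centroid of a geometry (exterior rings only)
#' @keywords internal
geom_centroid <- function(geom) {
  cx <- 0; cy <- 0; atot <- 0
  for (poly in geom) {
    ring <- poly[[1L]]
    x <- ring[, 1L]; y <- ring[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    cross <- x * yn - xn * y
    a <- sum(cross) / 2
    if (abs(a) < .Machine$double.eps) next
    cx <- cx + sum((x + xn) * cross) / 6
    cy <- cy + sum((y + yn) * cross) / 6
    atot <- atot + a
  }
  if (abs(atot) < .Machine$double.eps) {
    # fall back to vertex mean for zero-area input
    v <- do.call(rbind, lapply(geom, function(p) p[[1L]]))
    return(c(mean(v[, 1L]), mean(v[, 2L])))
  }
  c(cx / atot, cy / atot)
}

#' Bounding box of a geometry
#' @return numeric vector (xmin, ymin, xmax, ymax).
#' @keywords internal
geom_bbox <- function(geom) {
  v <- do.call(rbind, unlist(geom, recursive = FALSE))
  c(min(v[, 1L]), min(v[, 2L]), max(v[, 1L]), max(v[, 2L]))
}

# Distance tolerance (in map units, i.e. meters after projection) below which
# a point is treated as lying exactly on an edge.
.edge_tol <- 1e-9

#' Is a point on the boundary of a ring?
#' @keywords internal
point_on_ring <- function(px, py, ring, tol = .edge_tol) {
  x1 <- ring[, 1L]; y1 <- ring[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1 # degenerate edge -> treated as its first vertex
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  any((px - qx)^2 + (py - qy)^2 <= tol * tol)
}

#' Even-odd crossing test for one ring (boundary not handled here)
#' @keywords internal
point_in_ring_evenodd <- function(px, py, ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  crosses <- ((y > py) != (yn > py)) &
    (px < (xn - x) * (py - y) / (yn - y) + x)
  sum(crosses) %% 2L == 1L
}

#' Point-in-polygon test, boundary inclusive
#'
#' A point exactly on any ring edge counts as inside (closed polygon).
#' Interior membership uses the even-odd rule, so holes are excluded.
#'
#' @param px,py point coordinates.
#' @param geom a geometry (list of polygons, each a list of rings).
#' @param tol boundary tolerance in map units.
#' @return logical scalar.
#' @export
point_in_geom <- function(px, py, geom, tol = .edge_tol) {
  for (poly in geom) {
    for (ring in poly) {
      if (point_on_ring(px, py, ring, tol)) return(TRUE)
    }
    if (point_in_ring_evenodd(px, py, poly[[1L]])) {
      in_hole <- FALSE
      if (length(poly) > 1L) {
        for (h in poly[-1L]) {
          if (point_in_ring_evenodd(px, py, h)) { in_hole <- TRUE; break }
        }
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

#' Strict interior test (boundary points excluded)
#' @keywords internal
point_in_geom_interior <- function(px, py, geom, tol = .edge_tol) {
  for (poly in geom) {
    for (ring in poly) {
      if (point_on_ring(px, py, ring, tol)) return(FALSE)
    }
  }
  point_in_geom(px, py, geom, tol = 0)
}

# Do two closed segments properly intersect (cross in their interiors)?
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Validate a geometry: finite, positive area, no self-intersecting rings
#'
#' The self-intersection scan is quadratic per ring and only run for rings
#' small enough for that to be cheap; city admin boundaries qualify.
#'
#' @param geom a geometry.
#' @param max_vertices_checked skip the O(n^2) scan above this ring size.
#' @return invisibly TRUE; stops on invalid input.
#' @export
validate_geom <- function(geom, max_vertices_checked = 1500L) {
  if (length(geom) == 0L) stop("empty geometry", call. = FALSE)
  if (geom_area(geom) <= 0) stop("geometry has non-positive area", call. = FALSE)
  for (poly in geom) {
    for (ring in poly) {
      n <- nrow(ring)
      if (n > max_vertices_checked) next
      idx <- seq_len(n)
      nxt <- c(idx[-1L], 1L)
      for (i in idx) {
        for (j in idx[idx > i + 1L]) {
          if (i == 1L && j == n) next # adjacent through closure
          if (.segments_cross(ring[i, ], ring[nxt[i], ],
                              ring[j, ], ring[nxt[j], ])) {
            stop("self-intersecting polygon ring", call. = FALSE)
          }
        }
      }
    }
  }
  invisible(TRUE)
}

#' Flatten a road network into an edge table
#'
#' @param roads a `road_network` or bare list of polyline matrices.
#' @return data.frame with columns x1, y1, x2, y2, one row per edge.
#' @export
road_edges <- function(roads) {
  segs <- if (inherits(roads, "road_network")) roads$segments else roads
  if (length(segs) == 0L) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  pieces <- lapply(segs, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) stop("polyline with < 2 vertices", call. = FALSE)
    if (any(!is.finite(m))) stop("non-finite polyline coordinates", call. = FALSE)
    n <- nrow(m)
    data.frame(x1 = m[-n, 1L], y1 = m[-n, 2L], x2 = m[-1L, 1L], y2 = m[-1L, 2L])
  })
  do.call(rbind, pieces)
}

#' Total length of a set of edges
#' @keywords internal
edges_length <- function(edges) {
  sum(sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2))
}

#' Closest point on a set of edges
#'
#' @param edges edge table from [road_edges()].
#' @param px,py query point.
#' @return list(x, y, dist) for the nearest location on any edge.
#' @export
closest_point_on_edges <- function(edges, px, py) {
  if (nrow(edges) == 0L) return(list(x = NA_real_, y = NA_real_,
                                     dist = Inf))
  dx <- edges$x2 - edges$x1; dy <- edges$y2 - edges$y1
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1
  t <- pmin(1, pmax(0, ((px - edges$x1) * dx + (py - edges$y1) * dy) / len2))
  qx <- edges$x1 + t * dx; qy <- edges$y1 + t * dy
  d2 <- (px - qx)^2 + (py - qy)^2
  i <- which.min(d2)
  list(x = qx[i], y = qy[i], dist = sqrt(d2[i]))
}

#' Length of edges clipped to a closed disc
#'
#' Exact clipping: each edge is parameterised as p(t) = p1 + t (p2 - p1),
#' t in [0, 1]; |p(t) - c|^2 <= r^2 is a quadratic in t whose root interval,
#' intersected with [0, 1], gives the in-disc fraction. No densification and
#' no polygonal buffer approximation, so there is no tolerance knob.
#'
#' @param edges edge table from [road_edges()].
#' @param cx,cy disc centre.
#' @param r disc radius (> 0). The disc is closed (distance <= r counts).
#' @return total clipped length in the same units as the coordinates.
#' @export
clip_edges_to_disc <- function(edges, cx, cy, r) {
  if (nrow(edges) == 0L) return(0)
  dx <- edges$x2 - edges$x1
  dy <- edges$y2 - edges$y1
  fx <- edges$x1 - cx
  fy <- edges$y1 - cy
  a <- dx * dx + dy * dy           # |d|^2
  b <- 2 * (fx * dx + fy * dy)
  c0 <- fx * fx + fy * fy - r * r
  out <- numeric(nrow(edges))

  deg <- a == 0                     # zero-length edges contribute nothing
  disc <- b * b - 4 * a * c0
  ok <- !deg & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    frac <- pmax(0, t2 - t1)
    out[ok] <- frac * sqrt(a[ok])
  }
  sum(out)
}
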