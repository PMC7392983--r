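# GeoJSON I/O on top of jsonlite. Only the subset the pipeline needs:
# FeatureCollections of Polygon / MultiPolygon (boundaries, subcity units)
# and LineString / MultiLineString (roads). Coordinates are written with 10
# significant digits so lon/lat round-trips stay below 1e-6 degrees.

.ring_from_coords <- function(coords) {
  normalize_ring(do.call(rbind, lapply(coords, function(p) {
    c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))
  })))
}

.geom_from_geojson <- function(g) {
  type <- g$type
  if (identical(type, "Polygon")) {
    list(lapply(g$coordinates, .ring_from_coords))
  } else if (identical(type, "MultiPolygon")) {
    lapply(g$coordinates, function(poly) lapply(poly, .ring_from_coords))
  } else {
    stop("unsupported geometry type for a boundary: ", type, call. = FALSE)
  }
}

.lines_from_geojson <- function(g) {
  line_matrix <- function(coords) {
    do.call(rbind, lapply(coords, function(p) {
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))
    }))
  }
  type <- g$type
  if (identical(type, "LineString")) {
    list(line_matrix(g$coordinates))
  } else if (identical(type, "MultiLineString")) {
    lapply(g$coordinates, line_matrix)
  } else {
    stop("unsupported geometry type for roads: ", type, call. = FALSE)
  }
}

.read_fc <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    stop(path, ": not a GeoJSON FeatureCollection", call. = FALSE)
  }
  fc$features
}

#' Read city boundaries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon/MultiPolygon features with
#' `city_id` and `country` properties, coordinates in lon/lat degrees.
#'
#' @param path file path.
#' @return list of boundaries, each a list(city_id, country, geom).
#' @export
read_boundaries_geojson <- function(path) {
  lapply(.read_fc(path), function(f) {
    pr <- f$properties
    if (is.null(pr$city_id) || is.null(pr$country)) {
      stop(path, ": boundary feature lacks city_id/country", call. = FALSE)
    }
    list(city_id = as.character(pr$city_id),
         country = as.character(pr$country),
         geom = .geom_from_geojson(f$geometry))
  })
}

#' Read subcity units from GeoJSON
#'
#' FeatureCollection of Polygon/MultiPolygon features with `subcity_id`,
#' `city_id`, `country`, and `area_km2` properties.
#'
#' @param path file path.
#' @return list of units (subcity_id, city_id, country, area_km2, geom).
#' @export
read_units_geojson <- function(path) {
  lapply(.read_fc(path), function(f) {
    pr <- f$properties
    if (is.null(pr$subcity_id) || is.null(pr$area_km2)) {
      stop(path, ": unit feature lacks subcity_id/area_km2", call. = FALSE)
    }
    list(subcity_id = as.character(pr$subcity_id),
         city_id = as.character(pr$city_id %||% NA_character_),
         country = as.character(pr$country %||% NA_character_),
         area_km2 = as.numeric(pr$area_km2),
         geom = .geom_from_geojson(f$geometry))
  })
}

#' Read road polylines from GeoJSON
#'
#' FeatureCollection of LineString/MultiLineString features; an optional
#' `city_id` property groups roads by city.
#'
#' @param path file path.
#' @return list with `segments` (list of coordinate matrices) and
#'   `city_id` (vector aligned with segments, NA when absent).
#' @export
read_roads_geojson <- function(path) {
  segments <- list(); city_id <- character(0)
  for (f in .read_fc(path)) {
    segs <- .lines_from_geojson(f$geometry)
    cid <- as.character(f$properties$city_id %||% NA_character_)
    segments <- c(segments, segs)
    city_id <- c(city_id, rep(cid, length(segs)))
  }
  list(segments = segments, city_id = city_id)
}

.close_ring <- function(ring) rbind(ring, ring[1L, , drop = FALSE])

.geojson_polygon <- function(geom) {
  if (length(geom) == 1L) {
    list(type = "Polygon",
         coordinates = lapply(geom[[1L]], .close_ring))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(geom, function(p) lapply(p, .close_ring)))
  }
}

.write_fc <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(10))
  invisible(path)
}

#' Write polygon features (boundaries or units) to GeoJSON
#'
#' @param items list of lists, each with a `geom` and property fields.
#' @param path output path.
#' @param property_fields names of the fields to copy into `properties`.
#' @export
write_polygons_geojson <- function(items, path, property_fields) {
  features <- lapply(items, function(it) {
    list(type = "Feature",
         properties = it[property_fields],
         geometry = .geojson_polygon(it$geom))
  })
  .write_fc(features, path)
}

#' Write road polylines to GeoJSON
#'
#' @param segments list of coordinate matrices.
#' @param path output path.
#' @param city_id optional vector of city ids, one per segment.
#' @export
write_roads_geojson <- function(segments, path, city_id = NULL) {
  features <- lapply(seq_along(segments), function(i) {
    props <- if (is.null(city_id)) structure(list(), names = character(0))
             else list(city_id = city_id[i])
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = segments[[i]]))
  })
  .write_fc(features, path)
}
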