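# Imagery-metadata provider abstraction. The pipeline only ever talks to
# `query_metadata()`, so the bundled deterministic synthetic provider and
# the optional HTTP adapter are interchangeable.

#' Create a synthetic imagery-metadata provider
#'
#' A pure function of its panorama store: repeated queries always agree.
#' Nearest-panorama search is an exhaustive scan (the reference contract
#' for any faster index).
#'
#' @param panoramas data.frame with columns pano_id, x, y, capture_year,
#'   capture_month (planar meters in the same frame as the sample points).
#' @param fail_ids character vector of point ids for which the provider
#'   simulates a request failure (status ERROR).
#' @return an object of class `synthetic_provider`.
#' @export
synthetic_provider <- function(panoramas, fail_ids = character(0)) {
  need <- c("pano_id", "x", "y", "capture_year", "capture_month")
  if (!all(need %in% names(panoramas))) {
    stop("panorama store needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(panoramas) > 0L) {
    bad <- panoramas$capture_month < 1 | panoramas$capture_month > 12
    if (any(bad)) stop("capture_month outside 1..12", call. = FALSE)
  }
  structure(list(panoramas = panoramas, fail_ids = as.character(fail_ids)),
            class = c("synthetic_provider", "imagery_provider"))
}

#' @exportS3Method base::print
print.synthetic_provider <- function(x, ...) {
  cat(sprintf("<synthetic_provider> %d panoramas, %d configured failures\n",
              nrow(x$panoramas), length(x$fail_ids)))
  invisible(x)
}

.metadata <- function(status, year = NA_integer_, month = NA_integer_,
                      pano_x = NA_real_, pano_y = NA_real_,
                      pano_id = NA_character_, distance_m = NA_real_) {
  list(status = status, capture_year = year, capture_month = month,
       pano_x = pano_x, pano_y = pano_y, pano_id = pano_id,
       distance_m = distance_m)
}

#' Query imagery metadata for one point
#'
#' Returns `ZERO_RESULTS` if no panorama lies within `radius_m` (Euclidean)
#' of the point, otherwise `OK` with the closest panorama's capture date.
#' Panoramas at equal distance (within 1e-9 m) are broken by most recent
#' capture date, then smallest `pano_id`.
#'
#' @param provider an imagery provider.
#' @param x,y query point coordinates in meters.
#' @param radius_m search radius (default 100 m).
#' @param point_id optional id used by providers that simulate failures.
#' @return list with status (OK / ZERO_RESULTS / ERROR), capture_year,
#'   capture_month, pano_x, pano_y, pano_id, distance_m.
#' @export
query_metadata <- function(provider, x, y, radius_m = 100,
                           point_id = NA_character_) {
  UseMethod("query_metadata")
}

#' @export
query_metadata.synthetic_provider <- function(provider, x, y, radius_m = 100,
                                              point_id = NA_character_) {
  if (!is.na(point_id) && point_id %in% provider$fail_ids) {
    return(.metadata("ERROR"))
  }
  p <- provider$panoramas
  if (nrow(p) == 0L) return(.metadata("ZERO_RESULTS"))
  d <- sqrt((p$x - x)^2 + (p$y - y)^2)
  within <- d <= radius_m
  if (!any(within)) return(.metadata("ZERO_RESULTS"))
  dmin <- min(d[within])
  cand <- which(within & d <= dmin + 1e-9)
  if (length(cand) > 1L) {
    key <- p$capture_year[cand] * 12L + p$capture_month[cand]
    cand <- cand[key == max(key)]
    if (length(cand) > 1L) cand <- cand[order(p$pano_id[cand])][1L]
  }
  i <- cand[1L]
  .metadata("OK", as.integer(p$capture_year[i]), as.integer(p$capture_month[i]),
            p$x[i], p$y[i], p$pano_id[i], d[i])
}

#' Skeleton adapter for a live street-imagery metadata HTTP API
#'
#' Conforms to the provider interface but performs no network I/O here:
#' `query_metadata()` on it returns `ERROR` unless a `fetch` function is
#' injected. It exists so a real API client can be slotted in without
#' touching the pipeline; it is untested against any live service and does
#' no key management beyond carrying the string.
#'
#' @param base_url metadata endpoint.
#' @param api_key API key string.
#' @param fetch optional function(url) -> list(status, year, month, x, y)
#'   supplied by the caller (e.g. wrapping curl).
#' @return an object of class `http_provider`.
#' @export
http_provider <- function(base_url, api_key = "", fetch = NULL) {
  structure(list(base_url = base_url, api_key = api_key, fetch = fetch),
            class = c("http_provider", "imagery_provider"))
}

#' @export
query_metadata.http_provider <- function(provider, x, y, radius_m = 100,
                                         point_id = NA_character_) {
  if (is.null(provider$fetch)) return(.metadata("ERROR"))
  url <- sprintf("%s?location=%.8f,%.8f&radius=%d&key=%s",
                 provider$base_url, y, x, as.integer(radius_m),
                 provider$api_key)
  res <- tryCatch(provider$fetch(url), error = function(e) NULL)
  if (is.null(res) || is.null(res$status)) return(.metadata("ERROR"))
  if (!identical(res$status, "OK")) return(.metadata(res$status))
  .metadata("OK", res$year, res$month, res$x, res$y)
}

#' Audit eligible points against an imagery provider
#'
#' Annotates every point with its metadata status, capture date, and image
#' age, and reports OK / ZERO_RESULTS / ERROR counts and percentages.
#' ERROR points stay in the returned frame (they are part of the audit
#' record) but carry `available = NA` so downstream complete-case analysis
#' drops them.
#'
#' @param points data.frame of eligible sample points (point_id, x, y).
#' @param provider an imagery provider.
#' @param radius_m metadata search radius (default 100 m).
#' @param ref_year,ref_month reference date for image age (default 2019-04).
#' @return list with `frame` (audited points) and `report` (counts and
#'   percentages; percentages at full precision, rounded only for display).
#' @export
audit_points <- function(points, provider, radius_m = 100,
                         ref_year = 2019, ref_month = 4) {
  n <- nrow(points)
  status <- character(n)
  year <- integer(n); month <- integer(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    m <- query_metadata(provider, points$x[i], points$y[i], radius_m,
                        point_id = points$point_id[i])
    status[i] <- m$status
    year[i] <- m$capture_year %||% NA_integer_
    month[i] <- m$capture_month %||% NA_integer_
    dist[i] <- m$distance_m %||% NA_real_
  }
  out <- points
  out$status <- status
  out$capture_year <- year
  out$capture_month <- month
  out$pano_distance_m <- dist
  out$available <- ifelse(status == "ERROR", NA, status == "OK")
  out$age_months <- NA_real_
  ok <- which(status == "OK")
  if (length(ok)) {
    out$age_months[ok] <- image_age_months(year[ok], month[ok],
                                           ref_year, ref_month)
  }
  list(frame = out, report = availability_report(out))
}

#' Audit a random subsample of the excluded (road-free) points
#'
#' Draws a seeded simple random sample without replacement and returns the
#' fraction of sampled points for which the provider reports imagery --
#' the validation check that discarding road-free points loses almost no
#' imaged locations.
#'
#' @param excluded data.frame of ineligible points (road_length_m == 0).
#' @param provider an imagery provider.
#' @param sample_n sample size (<= nrow(excluded)).
#' @param seed integer RNG seed.
#' @param radius_m metadata search radius (default 100 m).
#' @return list with `proportion_ok` (fraction in \[0, 1\]), `n_ok`,
#'   `n_sampled`.
#' @export
validate_excluded <- function(excluded, provider, sample_n, seed,
                              radius_m = 100) {
  if (sample_n > nrow(excluded)) {
    stop("sample_n exceeds the number of excluded points", call. = FALSE)
  }
  set.seed(as.integer(seed))
  take <- sample.int(nrow(excluded), sample_n, replace = FALSE)
  sub <- excluded[take, , drop = FALSE]
  ok <- 0L
  for (i in seq_len(nrow(sub))) {
    m <- query_metadata(provider, sub$x[i], sub$y[i], radius_m,
                        point_id = sub$point_id[i])
    if (identical(m$status, "OK")) ok <- ok + 1L
  }
  list(proportion_ok = ok / sample_n, n_ok = ok, n_sampled = sample_n)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
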