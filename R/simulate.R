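# Synthetic cities with known ground truth. A city is a square boundary
# holding a rectangular road grid and a vertical-strip subcity partition.
# One latent socioeconomic factor per unit drives all covariates, panorama
# retention (availability), and capture-date age, so both model families
# have a recoverable truth.

#' Configuration for one synthetic city
#'
#' Defaults describe a mid-sized audit-scale city: a 5-km square (~121
#' lattice points at 500-m spacing), 4 subcity units, a 300-m road grid,
#' unit SES factors with SD 1, baseline availability near 45% (the
#' observed continent-wide rate), a mean image age of 55 months before
#' April 2019 with between-unit SD 6 and within-unit SD 18 months, and
#' candidate panoramas every 50 m of road.
#'
#' @param city_size_m side of the square boundary (meters).
#' @param n_subcities number of vertical-strip subcity units (>= 1).
#' @param road_grid_spacing_m base spacing of the rectangular road grid.
#' @param ses_between_sd SD of the latent SES factor across units.
#' @param beta0_avail,beta_ses_avail,beta_road_avail logistic coefficients
#'   for panorama retention: intercept, per-SD latent SES, per-SD local
#'   road density.
#' @param age_mean_months,beta_ses_age linear age model: baseline mean age
#'   and months-per-SD SES decrease (positive value = richer units have
#'   newer imagery).
#' @param age_unit_sd,age_within_sd unit-level and panorama-level age noise
#'   (months).
#' @param panorama_spacing_m spacing of candidate panorama sites along
#'   roads (site mode).
#' @param availability_mode `"site"` (default): candidate sites along the
#'   roads are retained independently with the logistic probability, so
#'   the coefficients govern per-site retention and point-level
#'   availability emerges from local site density. `"point"`: one
#'   Bernoulli draw per prospective 500-m lattice point (disc-disjoint at
#'   that spacing), with a retained panorama snapped to the nearest road
#'   location, so the logistic coefficients are exactly the point-level
#'   truth -- the mode used for parameter-recovery studies.
#' @param sample_spacing_m,audit_radius_m lattice spacing and metadata
#'   radius assumed by point mode (must match the audit settings).
#' @return a `synthetic_city_config` list.
#' @export
synthetic_city_config <- function(city_size_m = 5000,
                                  n_subcities = 4,
                                  road_grid_spacing_m = 300,
                                  ses_between_sd = 1,
                                  beta0_avail = -2.2,
                                  beta_ses_avail = 0.3,
                                  beta_road_avail = 0.2,
                                  age_mean_months = 55,
                                  beta_ses_age = 3,
                                  age_unit_sd = 6,
                                  age_within_sd = 18,
                                  panorama_spacing_m = 50,
                                  availability_mode = c("site", "point"),
                                  sample_spacing_m = 500,
                                  audit_radius_m = 100) {
  cfg <- list(city_size_m = city_size_m, n_subcities = as.integer(n_subcities),
              road_grid_spacing_m = road_grid_spacing_m,
              ses_between_sd = ses_between_sd,
              beta0_avail = beta0_avail, beta_ses_avail = beta_ses_avail,
              beta_road_avail = beta_road_avail,
              age_mean_months = age_mean_months, beta_ses_age = beta_ses_age,
              age_unit_sd = age_unit_sd, age_within_sd = age_within_sd,
              panorama_spacing_m = panorama_spacing_m,
              availability_mode = match.arg(availability_mode),
              sample_spacing_m = sample_spacing_m,
              audit_radius_m = audit_radius_m)
  stopifnot(cfg$city_size_m > 0, cfg$n_subcities >= 1L,
            cfg$road_grid_spacing_m > 0, cfg$panorama_spacing_m > 0,
            cfg$ses_between_sd >= 0, cfg$age_unit_sd >= 0,
            cfg$age_within_sd >= 0)
  class(cfg) <- "synthetic_city_config"
  cfg
}

.square_ring <- function(size) {
  rbind(c(0, 0), c(size, 0), c(size, size), c(0, size))
}

# Walk a polyline placing sites every `step` meters (including the start).
.sites_along <- function(seg, step) {
  n <- nrow(seg)
  dx <- diff(seg[, 1L]); dy <- diff(seg[, 2L])
  lens <- sqrt(dx^2 + dy^2)
  total <- sum(lens)
  if (total < step) return(cbind(seg[1L, 1L], seg[1L, 2L]))
  s <- seq(0, total, by = step)
  cum <- c(0, cumsum(lens))
  piece <- findInterval(s, cum, rightmost.closed = TRUE)
  piece[piece > n - 1L] <- n - 1L
  frac <- (s - cum[piece]) / lens[piece]
  cbind(seg[piece, 1L] + frac * dx[piece],
        seg[piece, 2L] + frac * dy[piece])
}

#' Simulate one city with known ground truth
#'
#' The boundary is a `city_size_m` square; subcity units are equal-width
#' vertical strips; roads form a rectangular grid whose vertical-line
#' spacing within each strip tightens with the unit's SES factor (denser
#' streets in better-off units); candidate panorama sites sit every
#' `panorama_spacing_m` along the roads and are retained with probability
#' `plogis(beta0 + beta_ses * SES + beta_road * road_density_z)`; retained
#' panoramas get an age drawn from
#' `Normal(age_mean - beta_ses_age * SES + unit_effect, age_within_sd)`,
#' truncated at 0, rounded to whole months, and converted to a capture
#' year-month before the April 2019 reference. Everything is reproducible
#' from the seed.
#'
#' @param config a `synthetic_city_config`.
#' @param seed integer seed.
#' @param city_id,country identifiers for the generated city.
#' @param center_lonlat notional geographic centre (degrees), giving the
#'   planar frame an invertible lon/lat mapping.
#' @return a `synthetic_city`: boundary, roads, units (with covariates),
#'   panoramas, truth.
#' @export
simulate_city <- function(config = synthetic_city_config(), seed = 1L,
                          city_id = "SIM001", country = "BR",
                          center_lonlat = c(-55, -15)) {
  set.seed(as.integer(seed))
  size <- config$city_size_m
  crs <- list(type = "aeqd_sphere", lon0 = center_lonlat[1L],
              lat0 = center_lonlat[2L], radius_m = EARTH_RADIUS_M)
  boundary <- structure(
    list(city_id = city_id, country = country,
         geom = list(list(.square_ring(size))), crs = crs),
    class = "city_boundary")

  nu <- config$n_subcities
  strip_w <- size / nu
  ses <- stats::rnorm(nu, 0, config$ses_between_sd)

  # covariates: one latent factor, covariate-specific loadings and noise,
  # percents clipped to [0, 100], density log-normal around 5000 persons/km2
  clip01 <- function(v) pmin(100, pmax(0, v))
  cov_tbl <- data.frame(
    subcity_id = sprintf("%s_U%02d", city_id, seq_len(nu)),
    city_id = city_id, country = country,
    area_km2 = strip_w * size / 1e6,
    pop_density = exp(log(5000) + 0.3 * ses + stats::rnorm(nu, 0, 0.15)),
    pct_piped_water = clip01(75 + 12 * ses + stats::rnorm(nu, 0, 4)),
    pct_sewer = clip01(60 + 15 * ses + stats::rnorm(nu, 0, 5)),
    pct_durable_walls = clip01(80 + 10 * ses + stats::rnorm(nu, 0, 4)),
    pct_labor = clip01(55 + 6 * ses + stats::rnorm(nu, 0, 3)),
    pct_secondary_edu = clip01(40 + 13 * ses + stats::rnorm(nu, 0, 5)),
    pct_above_poverty = clip01(65 + 14 * ses + stats::rnorm(nu, 0, 5)),
    ses_truth = ses,
    stringsAsFactors = FALSE)

  units <- lapply(seq_len(nu), function(u) {
    ring <- rbind(c((u - 1L) * strip_w, 0), c(u * strip_w, 0),
                  c(u * strip_w, size), c((u - 1L) * strip_w, size))
    list(subcity_id = cov_tbl$subcity_id[u], city_id = city_id,
         country = country, area_km2 = cov_tbl$area_km2[u],
         geom = list(list(ring)))
  })

  # roads: horizontal lines city-wide; vertical lines per strip, spacing
  # shrinking with SES (about -13% per SD)
  segs <- list()
  ys <- seq(0, size, by = config$road_grid_spacing_m)
  for (y in ys) segs[[length(segs) + 1L]] <- rbind(c(0, y), c(size, y))
  for (u in seq_len(nu)) {
    sp_u <- config$road_grid_spacing_m * exp(-0.12 * ses[u])
    xs <- seq((u - 1L) * strip_w, u * strip_w, by = sp_u)
    for (x in xs) segs[[length(segs) + 1L]] <- rbind(c(x, 0), c(x, size))
  }
  if (length(segs) == 0L) stop("degenerate config: no roads", call. = FALSE)
  roads <- structure(list(segments = segs, crs = crs), class = "road_network")

  edges <- road_edges(roads)
  if (config$availability_mode == "site") {
    # candidate panorama sites along every road polyline, retained
    # independently with the logistic probability
    sites <- do.call(rbind, lapply(segs, .sites_along,
                                   step = config$panorama_spacing_m))
    if (is.null(sites) || nrow(sites) == 0L) {
      stop("degenerate config: no candidate panorama sites", call. = FALSE)
    }
  } else {
    # one candidate per prospective lattice point, snapped to the nearest
    # road; 500-m spacing keeps the 100-m audit discs disjoint, so each
    # audited point's availability is exactly one Bernoulli draw
    grid <- generate_point_grid(boundary, config$sample_spacing_m)
    if (nrow(grid) == 0L) {
      stop("degenerate config: no lattice points", call. = FALSE)
    }
    snapped <- lapply(seq_len(nrow(grid)), function(i) {
      closest_point_on_edges(edges, grid$x[i], grid$y[i])
    })
    dist <- vapply(snapped, `[[`, numeric(1), "dist")
    near <- which(dist <= config$audit_radius_m) # audit-eligible points only
    if (length(near) == 0L) {
      stop("degenerate config: no candidate panorama sites", call. = FALSE)
    }
    sites <- cbind(vapply(snapped[near], `[[`, numeric(1), "x"),
                   vapply(snapped[near], `[[`, numeric(1), "y"))
  }
  site_unit <- pmin(nu, pmax(1L, floor(sites[, 1L] / strip_w) + 1L))
  density <- vapply(seq_len(nrow(sites)), function(i) {
    clip_edges_to_disc(edges, sites[i, 1L], sites[i, 2L], 100)
  }, numeric(1))
  dz <- if (stats::sd(density) > 0) (density - mean(density)) / stats::sd(density)
        else rep(0, length(density))
  eta <- config$beta0_avail + config$beta_ses_avail * ses[site_unit] +
    config$beta_road_avail * dz
  keep <- stats::runif(nrow(sites)) < stats::plogis(eta)

  unit_eff <- stats::rnorm(nu, 0, config$age_unit_sd)
  kept <- which(keep)
  ages <- pmax(0, stats::rnorm(
    length(kept),
    config$age_mean_months - config$beta_ses_age * ses[site_unit[kept]] +
      unit_eff[site_unit[kept]],
    config$age_within_sd))
  ages <- as.integer(round(ages))
  # months-before-2019-04 -> capture year-month
  tot <- 2019L * 12L + 4L - 1L - ages          # zero-based month index
  cap_year <- tot %/% 12L
  cap_month <- tot %% 12L + 1L
  panoramas <- data.frame(
    pano_id = sprintf("%s_P%06d", city_id, seq_along(kept)),
    x = sites[kept, 1L], y = sites[kept, 2L],
    capture_year = cap_year, capture_month = cap_month,
    subcity_id = cov_tbl$subcity_id[site_unit[kept]],
    age_truth_months = ages,
    stringsAsFactors = FALSE)

  structure(list(
    boundary = boundary, roads = roads, units = units,
    covariates = cov_tbl, panoramas = panoramas,
    truth = list(config = config, seed = as.integer(seed), ses = ses,
                 unit_age_effects = unit_eff,
                 n_candidate_sites = nrow(sites))),
    class = "synthetic_city")
}

#' @exportS3Method base::print
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %s (%s): %.0f-m square, %d units, %d roads, %d panoramas\n",
              x$boundary$city_id, x$boundary$country,
              x$truth$config$city_size_m, length(x$units),
              length(x$roads$segments), nrow(x$panoramas)))
  invisible(x)
}

#' Simulate a multi-city study
#'
#' Draws `n_cities` synthetic cities with sizes varying uniformly over
#' `size_range_m` and road-grid spacings over `road_spacing_range_m`,
#' assigning country labels round-robin over six levels (the five large
#' countries and a pooled Central-America level). Each city gets an
#' independent sub-seed derived from `seed`.
#'
#' @param n_cities number of cities (>= 2).
#' @param config base `synthetic_city_config`; per-city size/spacing are
#'   overridden from the ranges.
#' @param seed integer master seed.
#' @param size_range_m,road_spacing_range_m uniform ranges for city side
#'   and road-grid spacing.
#' @param countries country labels cycled over the cities.
#' @return list of class `synthetic_study`: cities (list of
#'   `synthetic_city`), covariates (row-bound unit table), truth.
#' @export
simulate_study <- function(n_cities = 20, config = synthetic_city_config(),
                           seed = 1L,
                           size_range_m = c(3000, 6000),
                           road_spacing_range_m = c(250, 400),
                           countries = c("AR", "BR", "CO", "MX", "PE", "CA")) {
  stopifnot(n_cities >= 2L)
  set.seed(as.integer(seed))
  sizes <- stats::runif(n_cities, size_range_m[1L], size_range_m[2L])
  spacings <- stats::runif(n_cities, road_spacing_range_m[1L],
                           road_spacing_range_m[2L])
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n_cities)
  lon0 <- stats::runif(n_cities, -75, -40)
  lat0 <- stats::runif(n_cities, -30, 10)
  cities <- vector("list", n_cities)
  for (i in seq_len(n_cities)) {
    cfg_i <- config
    cfg_i$city_size_m <- sizes[i]
    cfg_i$road_grid_spacing_m <- spacings[i]
    cities[[i]] <- simulate_city(
      cfg_i, seed = sub_seeds[i],
      city_id = sprintf("SIM%03d", i),
      country = countries[(i - 1L) %% length(countries) + 1L],
      center_lonlat = c(lon0[i], lat0[i]))
  }
  structure(list(
    cities = cities,
    covariates = do.call(rbind, lapply(cities, `[[`, "covariates")),
    truth = list(config = config, seed = as.integer(seed),
                 sub_seeds = sub_seeds)),
    class = "synthetic_study")
}

#' Run the audit pipeline over a synthetic study
#'
#' Sample lattice, road-length eligibility, subcity assignment, and imagery
#' audit for every city, using each city's panorama store as its synthetic
#' provider.
#'
#' @param study a `synthetic_study`.
#' @param spacing_m lattice spacing (default 500 m).
#' @param radius_m buffer / metadata radius (default 100 m).
#' @return list: frame (audited eligible points across cities, ERROR-free),
#'   all_points (full sample frame incl. ineligible), units (covariate
#'   table), report (pooled availability report).
#' @export
audit_study <- function(study, spacing_m = 500, radius_m = 100) {
  frames <- list(); alls <- list()
  for (ct in study$cities) {
    sf <- build_sample_frame(ct$boundary, ct$roads, ct$units,
                             spacing_m = spacing_m, radius_m = radius_m)
    alls[[length(alls) + 1L]] <- sf
    el <- filter_eligible(sf)
    if (nrow(el) == 0L) next
    provider <- synthetic_provider(ct$panoramas)
    aud <- audit_points(el, provider, radius_m = radius_m)
    frames[[length(frames) + 1L]] <- aud$frame
  }
  frame <- do.call(rbind, frames)
  list(frame = frame, all_points = do.call(rbind, alls),
       units = study$covariates, report = availability_report(frame))
}
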