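# Fixtures and independent oracles used across the suite. Oracles are
# deliberately implemented with different algorithms than the package
# (winding-number point-in-polygon, densification length, IRLS and
# normal-equation fits) so agreement is evidence, not tautology.

# --- fixtures ---------------------------------------------------------------

# A planar city_boundary without projection (coordinates already meters).
planar_boundary <- function(ring, city_id = "T1", country = "BR") {
  structure(list(city_id = city_id, country = country,
                 geom = list(list(ring)), crs = NULL),
            class = "city_boundary")
}

square_ring <- function(size, x0 = 0, y0 = 0) {
  rbind(c(x0, y0), c(x0 + size, y0), c(x0 + size, y0 + size), c(x0, y0 + size))
}

# Star-shaped random polygon around the origin: always simple.
random_star_polygon <- function(n_vertices = 8, r_min = 400, r_max = 1500) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, r_min, r_max)
  cbind(rad * cos(ang), rad * sin(ang))
}

# Random small road network: a few polylines in a box.
random_road_network <- function(n_lines = 4, extent = 600, max_vertices = 4) {
  segs <- lapply(seq_len(n_lines), function(i) {
    nv <- sample(2:max_vertices, 1)
    cbind(stats::runif(nv, -extent, extent), stats::runif(nv, -extent, extent))
  })
  structure(list(segments = segs), class = "road_network")
}

# --- geometry oracles -------------------------------------------------------

# Winding-number point-in-polygon (vs the package's even-odd ray cast).
# Boundary-inclusive like the stated contract: points on an edge are inside.
winding_inside <- function(px, py, ring, tol = 1e-9) {
  x <- ring[, 1L] - px; y <- ring[, 2L] - py
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  # on-edge check via segment distance
  dx <- xn - x; dy <- yn - y
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- 1
  t <- pmin(1, pmax(0, -(x * dx + y * dy) / len2))
  if (min((x + t * dx)^2 + (y + t * dy)^2) <= tol * tol) return(TRUE)
  ang <- atan2(x * yn - xn * y, x * xn + y * yn)
  abs(sum(ang)) > pi # winding number != 0
}

# Exhaustive lattice oracle: enumerate all bbox lattice points, test with the
# winding-number rule.
oracle_grid_count <- function(ring, spacing) {
  bb <- c(min(ring[, 1L]), min(ring[, 2L]), max(ring[, 1L]), max(ring[, 2L]))
  xs <- seq(bb[1L], bb[3L] + spacing * 1e-9, by = spacing)
  ys <- seq(bb[2L], bb[4L] + spacing * 1e-9, by = spacing)
  n <- 0L
  for (y in ys) for (x in xs) if (winding_inside(x, y, ring)) n <- n + 1L
  n
}

# Densification oracle for disc-clipped road length: cut every edge into
# `step`-long pieces and sum pieces whose midpoints fall inside the disc.
oracle_disc_length <- function(roads, cx, cy, r, step = 0.01) {
  edges <- road_edges(roads)
  total <- 0
  for (i in seq_len(nrow(edges))) {
    dx <- edges$x2[i] - edges$x1[i]; dy <- edges$y2[i] - edges$y1[i]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) next
    k <- ceiling(len / step)
    mid <- (seq_len(k) - 0.5) / k
    mx <- edges$x1[i] + mid * dx; my <- edges$y1[i] + mid * dy
    total <- total + sum((mx - cx)^2 + (my - cy)^2 <= r * r) * len / k
  }
  total
}

# --- model oracles ----------------------------------------------------------

# Logistic regression by hand-rolled Newton-Raphson IRLS.
oracle_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    delta <- solve(info, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coef = beta, se = se)
}

# OLS via explicit normal equations.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = drop(beta), se = sqrt(diag(s2 * solve(XtX))))
}

# One recovery-study replicate: simulate a 12-city study in point-availability
# mode (the logistic coefficients are then the exact point-level truth), audit
# it, and fit both model families with the latent SES factor as exposure.
# Returns estimate / se / p for the logistic (availability) and linear
# (mean age) fits.
acceptance_replicate <- function(seed, beta_avail, beta_age) {
  cfg <- synthetic_city_config(
    availability_mode = "point", beta0_avail = -0.2,
    beta_ses_avail = beta_avail, beta_road_avail = 0,
    beta_ses_age = beta_age, age_unit_sd = 6, age_within_sd = 18,
    n_subcities = 4)
  st <- simulate_study(n_cities = 12, config = cfg, seed = seed,
                       size_range_m = c(2500, 4000))
  aud <- audit_study(st)
  d <- build_availability_design(aud$frame, aud$units, "ses_truth")
  fit_l <- fit_availability_model(d)
  summ <- summarize_units(aud$frame, "subcity_id")
  d2 <- build_subcity_design(summ, aud$units, "mean_age_months", "ses_truth")
  fit_a <- fit_subcity_model(d2)
  c(b_l = unname(fit_l$b), se_l = unname(fit_l$se), p_l = unname(fit_l$p),
    b_a = unname(fit_a$b), se_a = unname(fit_a$se), p_a = unname(fit_a$p))
}

# --- small synthetic datasets ----------------------------------------------

# Tiny audited frame + unit table built directly (no geometry) for model
# plumbing tests.
tiny_model_data <- function(seed = 1, n_cities = 6, units_per_city = 3,
                            points_per_unit = 25, beta_ses = 0.4) {
  set.seed(seed)
  rows <- list(); units <- list()
  countries <- c("AR", "BR", "CO", "MX", "PE", "CA")
  for (ci in seq_len(n_cities)) {
    cid <- sprintf("C%02d", ci)
    for (ui in seq_len(units_per_city)) {
      uid <- sprintf("%s_U%d", cid, ui)
      ses <- stats::rnorm(1)
      units[[length(units) + 1L]] <- data.frame(
        subcity_id = uid, city_id = cid,
        country = countries[(ci - 1L) %% 6L + 1L],
        area_km2 = stats::runif(1, 5, 50),
        pop_density = exp(8 + 0.3 * ses + stats::rnorm(1, 0, 0.1)),
        pct_piped_water = pmin(100, pmax(0, 75 + 12 * ses + stats::rnorm(1, 0, 3))),
        pct_sewer = pmin(100, pmax(0, 60 + 15 * ses + stats::rnorm(1, 0, 3))),
        pct_durable_walls = pmin(100, pmax(0, 80 + 10 * ses + stats::rnorm(1, 0, 3))),
        pct_labor = pmin(100, pmax(0, 55 + 6 * ses + stats::rnorm(1, 0, 2))),
        pct_secondary_edu = pmin(100, pmax(0, 40 + 13 * ses + stats::rnorm(1, 0, 3))),
        pct_above_poverty = pmin(100, pmax(0, 65 + 14 * ses + stats::rnorm(1, 0, 3))),
        ses_truth = ses, stringsAsFactors = FALSE)
      np <- points_per_unit
      avail <- stats::runif(np) < stats::plogis(-0.2 + beta_ses * ses)
      age <- pmax(0, round(stats::rnorm(np, 55 - 3 * ses, 15)))
      rows[[length(rows) + 1L]] <- data.frame(
        point_id = sprintf("%s_P%03d", uid, seq_len(np)),
        city_id = cid, subcity_id = uid,
        x = stats::runif(np, 0, 3000) + ci * 10000,
        y = stats::runif(np, 0, 3000),
        road_length_m = stats::runif(np, 50, 400),
        eligible = TRUE,
        status = ifelse(avail, "OK", "ZERO_RESULTS"),
        available = avail,
        age_months = ifelse(avail, age, NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  list(frame = do.call(rbind, rows), units = do.call(rbind, units))
}
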