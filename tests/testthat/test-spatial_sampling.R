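# Lattice sampling, buffer road lengths, eligibility, subcity assignment.

test_that("project_city centres on the centroid and round-trips", {
  ring <- rbind(c(-70.01, -33.01), c(-69.99, -33.01),
                c(-69.99, -32.99), c(-70.01, -32.99))
  b <- list(city_id = "SCL1", country = "CL", geom = list(list(ring)))
  seg <- rbind(c(-70.005, -33.005), c(-69.995, -32.995))
  proj <- project_city(b, list(seg))

  ctr <- geom_centroid(b$geom)
  p0 <- aeqd_forward(ctr[1], ctr[2], proj$boundary$crs$lon0,
                     proj$boundary$crs$lat0)
  expect_equal(c(p0$x, p0$y), c(0, 0), tolerance = 1e-9)

  # round-trip every boundary vertex to < 1e-6 degrees
  pr <- proj$boundary$geom[[1]][[1]]
  ll <- aeqd_inverse(pr[, 1], pr[, 2], proj$boundary$crs$lon0,
                     proj$boundary$crs$lat0)
  expect_lt(max(abs(ll$lon - ring[, 1])), 1e-6)
  expect_lt(max(abs(ll$lat - ring[, 2])), 1e-6)
})

test_that("projected distances match the geodesic scale near the equator", {
  # two points 0.001 degrees apart in latitude ~ 111.32 m
  p <- aeqd_forward(c(0, 0), c(0, 0.001), lon0 = 0, lat0 = 0.0005)
  d <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  expect_lt(abs(d - 111.32) / 111.32, 0.001)
})

test_that("project_city refuses bad input", {
  expect_error(project_city(list(city_id = "X", country = "AR",
                                 geom = list())),
               "empty")
  big <- rbind(c(-60, -20), c(-45, -20), c(-45, -5), c(-60, -5))
  expect_error(project_city(list(city_id = "X", country = "AR",
                                 geom = list(list(big)))),
               "1000 km")
})

test_that("lattice counts on squares are exact and boundary-inclusive", {
  b <- planar_boundary(square_ring(1000))
  g <- generate_point_grid(b, 500)
  expect_equal(nrow(g), 9L) # 3 x 3 including all edges
  expect_equal(nrow(generate_point_grid(b, 2000)), 1L) # anchor corner only
  # row-major deterministic ordering
  expect_true(!is.unsorted(g$y))
  expect_identical(g, generate_point_grid(b, 500))
})

test_that("zero-area boundary warns and returns an empty frame", {
  degenerate <- planar_boundary(rbind(c(0, 0), c(100, 100), c(200, 200)))
  expect_warning(g <- generate_point_grid(degenerate, 50), "zero-area")
  expect_equal(nrow(g), 0L)
})

test_that("lattice counts match the exhaustive winding-number oracle", {
  set.seed(101)
  for (i in 1:100) {
    ring <- random_star_polygon(sample(5:12, 1))
    b <- planar_boundary(ring)
    got <- nrow(generate_point_grid(b, 300))
    expect_equal(got, oracle_grid_count(ring, 300),
                 info = sprintf("polygon %d", i))
  }
})

test_that("road_length_within handles the canonical cases", {
  # chord through the centre of a 100-m disc = the 200-m diameter
  seg <- rbind(c(-200, 0), c(200, 0))
  expect_equal(road_length_within(c(0, 0), list(seg), 100), 200)
  # everything further than the radius contributes nothing
  far <- rbind(c(-500, 101), c(500, 101))
  expect_equal(road_length_within(c(0, 0), list(far), 100), 0)
  # empty network
  expect_equal(road_length_within(c(0, 0), list(), 100), 0)
})

test_that("disc clipping matches the 1-cm densification oracle", {
  set.seed(202)
  for (i in 1:100) {
    roads <- random_road_network(n_lines = sample(2:4, 1), extent = 300)
    got <- road_length_within(c(0, 0), roads, 100)
    want <- oracle_disc_length(roads, 0, 0, 100)
    if (want > 1) {
      expect_lt(abs(got - want) / want, 0.001)
    } else {
      expect_lt(abs(got - want), 0.02)
    }
  }
})

test_that("road length is monotone in radius and in added segments", {
  set.seed(303)
  for (i in 1:25) {
    roads <- random_road_network(n_lines = 3, extent = 300)
    r1 <- road_length_within(c(0, 0), roads, 60)
    r2 <- road_length_within(c(0, 0), roads, 100)
    r3 <- road_length_within(c(0, 0), roads, 180)
    expect_true(r1 <= r2 + 1e-12 && r2 <= r3 + 1e-12)
    more <- structure(list(segments = c(roads$segments,
                                        list(rbind(c(-50, 0), c(50, 0))))),
                      class = "road_network")
    expect_gte(road_length_within(c(0, 0), more, 100) + 1e-12, r2)
  }
})

test_that("filter_eligible keeps exactly the positive road lengths", {
  pts <- data.frame(point_id = letters[1:5], road_length_m = c(0, 10, 0, 0.5, 200))
  kept <- filter_eligible(pts)
  expect_equal(kept$point_id, c("b", "d", "e"))
  expect_identical(filter_eligible(kept), kept) # idempotent
  none <- data.frame(road_length_m = c(0, 0))
  expect_equal(nrow(filter_eligible(none)), 0L)
  expect_error(filter_eligible(data.frame(x = 1)), "road_length_m")
})

test_that("subcity assignment is containment-exact with lexicographic ties", {
  unit_a <- list(subcity_id = "A", geom = list(list(square_ring(100))))
  unit_b <- list(subcity_id = "B", geom = list(list(square_ring(100, x0 = 100))))
  pts <- data.frame(x = c(50, 150, 100, 300), y = c(50, 50, 50, 50))
  out <- assign_subcity(pts, list(unit_b, unit_a)) # order must not matter
  expect_equal(out$subcity_id, c("A", "B", "A", NA)) # shared edge -> A
})

test_that("assignment matches brute-force containment on random points", {
  set.seed(404)
  units <- lapply(1:4, function(u) {
    list(subcity_id = sprintf("U%d", u),
         geom = list(list(square_ring(250, x0 = (u - 1) * 250))))
  })
  pts <- data.frame(x = runif(200, -50, 1050), y = runif(200, -50, 300))
  out <- assign_subcity(pts, units)
  for (i in seq_len(nrow(pts))) {
    inside <- vapply(units, function(u) {
      point_in_geom(pts$x[i], pts$y[i], u$geom)
    }, logical(1))
    want <- if (!any(inside)) NA_character_
            else sort(vapply(units[inside], `[[`, character(1), "subcity_id"))[1]
    expect_identical(out$subcity_id[i], want)
  }
  # conservation: assigned points = union of per-unit sets, no duplicates
  per_unit <- table(out$subcity_id)
  expect_equal(sum(per_unit), sum(!is.na(out$subcity_id)))
})

test_that("overlapping unit interiors are rejected", {
  units <- list(
    list(subcity_id = "A", geom = list(list(square_ring(100)))),
    list(subcity_id = "B", geom = list(list(square_ring(100, x0 = 50)))))
  pts <- data.frame(x = 75, y = 50)
  expect_error(assign_subcity(pts, units), "overlap")
})

test_that("build_sample_frame produces the documented schema", {
  ct <- simulate_city(synthetic_city_config(city_size_m = 2000,
                                            n_subcities = 2), seed = 5)
  sf <- build_sample_frame(ct$boundary, ct$roads, ct$units)
  expect_named(sf, c("point_id", "city_id", "subcity_id", "x", "y", "lon",
                     "lat", "road_length_m", "eligible"))
  expect_true(all(sf$eligible == (sf$road_length_m > 0)))
  expect_true(all(!is.na(sf$subcity_id))) # strips partition the square
  # lon/lat invert back to x/y
  xy <- aeqd_forward(sf$lon, sf$lat, ct$boundary$crs$lon0,
                     ct$boundary$crs$lat0)
  expect_lt(max(abs(xy$x - sf$x)), 1e-6)
})
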