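# Synthetic imagery provider: query semantics, audits, excluded-sample
# validation.

pano_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("pano_id", "x", "y", "capture_year", "capture_month")[seq_along(df)]
  df
}

test_that("query_metadata returns the closest panorama within the radius", {
  prov <- synthetic_provider(pano_df("p1", 50, 0, 2017, 6))
  m <- query_metadata(prov, 0, 0, 100)
  expect_equal(m$status, "OK")
  expect_equal(c(m$capture_year, m$capture_month), c(2017, 6))
  expect_equal(m$distance_m, 50)

  far <- synthetic_provider(pano_df("p1", 150, 0, 2017, 6))
  expect_equal(query_metadata(far, 0, 0, 100)$status, "ZERO_RESULTS")
  # closed radius: a panorama exactly at 100 m counts
  edge <- synthetic_provider(pano_df("p1", 100, 0, 2017, 6))
  expect_equal(query_metadata(edge, 0, 0, 100)$status, "OK")
})

test_that("distance ties resolve to the most recent image, then smallest id", {
  two <- synthetic_provider(pano_df(c("a", "b"), c(60, -60), c(0, 0),
                                    c(2012, 2018), c(1, 9)))
  m <- query_metadata(two, 0, 0, 100)
  expect_equal(c(m$capture_year, m$capture_month), c(2018, 9))
  same_date <- synthetic_provider(pano_df(c("b2", "a1"), c(60, -60), c(0, 0),
                                          c(2018, 2018), c(9, 9)))
  expect_equal(query_metadata(same_date, 0, 0, 100)$pano_id, "a1")
})

test_that("queries are deterministic and closest-first against exhaustive search", {
  set.seed(11)
  store <- pano_df(sprintf("p%02d", 1:40), runif(40, -200, 200),
                   runif(40, -200, 200), sample(2010:2019, 40, TRUE),
                   sample(1:12, 40, TRUE))
  prov <- synthetic_provider(store)
  for (k in 1:20) {
    qx <- runif(1, -150, 150); qy <- runif(1, -150, 150)
    m1 <- query_metadata(prov, qx, qy, 100)
    expect_identical(m1, query_metadata(prov, qx, qy, 100))
    d <- sqrt((store$x - qx)^2 + (store$y - qy)^2)
    if (m1$status == "OK") {
      expect_equal(m1$distance_m, min(d)) # exhaustive-scan agreement
      expect_lte(min(d), 100)
      # radius monotonicity: still OK at a larger radius
      expect_equal(query_metadata(prov, qx, qy, 180)$status, "OK")
    } else {
      expect_gt(min(d), 100)
    }
  }
})

test_that("audit_points annotates, reports, and conserves counts", {
  pts <- data.frame(point_id = sprintf("q%d", 1:4),
                    x = c(0, 0, 500, 500), y = c(0, 500, 0, 500))
  prov <- synthetic_provider(pano_df(c("p1", "p2"), c(10, 490), c(0, 510),
                                     c(2018, 2015), c(4, 10)))
  aud <- audit_points(pts, prov)
  expect_equal(aud$report$n_ok, 2L)
  expect_equal(aud$report$pct_ok, 50)
  expect_equal(aud$report$n_error, 0L)
  expect_equal(aud$report$n_ok + aud$report$n_zero_results +
                 aud$report$n_error, aud$report$n_audited)
  expect_equal(aud$frame$age_months[1], 12) # 2018-04 vs 2019-04
})

test_that("provider failures are recorded and drop from complete cases", {
  pts <- data.frame(point_id = sprintf("q%04d", 1:1000),
                    x = runif(1000), y = runif(1000))
  prov <- synthetic_provider(pano_df(character(0), numeric(0), numeric(0),
                                     integer(0), integer(0)),
                             fail_ids = "q0042")
  aud <- audit_points(pts, prov)
  expect_equal(aud$report$n_error, 1L)
  expect_equal(sum(!is.na(aud$frame$available)), 999L)
})

test_that("validate_excluded measures imagery among road-free points", {
  excluded <- data.frame(point_id = sprintf("e%d", 1:200),
                         x = seq(1000, 200900, by = 1000), y = 0)
  none <- synthetic_provider(pano_df(character(0), numeric(0), numeric(0),
                                     integer(0), integer(0)))
  expect_equal(validate_excluded(excluded, none, 50, seed = 1)$proportion_ok, 0)
  everywhere <- synthetic_provider(
    pano_df(sprintf("p%d", 1:200), excluded$x, excluded$y,
            rep(2018, 200), rep(1, 200)))
  expect_equal(validate_excluded(excluded, everywhere, 50, seed = 1)$proportion_ok, 1)
  # seeded draws reproduce; sample_n guard
  r1 <- validate_excluded(excluded, everywhere, 20, seed = 9)
  r2 <- validate_excluded(excluded, everywhere, 20, seed = 9)
  expect_identical(r1, r2)
  expect_error(validate_excluded(excluded, none, 500, seed = 1), "sample_n")
})

test_that("the http adapter degrades to ERROR without a fetch function", {
  prov <- http_provider("https://example.invalid/meta")
  expect_equal(query_metadata(prov, 0, 0, 100)$status, "ERROR")
  stub <- http_provider("x", fetch = function(url) {
    list(status = "OK", year = 2016, month = 2, x = 1, y = 2)
  })
  m <- query_metadata(stub, 0, 0, 100)
  expect_equal(c(m$capture_year, m$capture_month), c(2016, 2))
})
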