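# Design assembly and model fitting for the availability and subcity-age
# model families.

test_that("standardize_xy standardises per city and is translation-invariant", {
  pts <- data.frame(city_id = "C1", x = c(0, 500, 1000), y = c(0, 0, 500))
  s <- standardize_xy(pts)
  expect_equal(s$x_std, c(-1, 0, 1))
  expect_equal(mean(s$y_std), 0, tolerance = 1e-12)
  expect_equal(sd(s$y_std), 1, tolerance = 1e-12)
  shifted <- transform(pts, x = x + 1e5, y = y - 2e4)
  s2 <- standardize_xy(shifted)
  expect_equal(s2$x_std, s$x_std)
  expect_equal(s2$y_std, s$y_std)
  w <- capture_warnings(s1 <- standardize_xy(data.frame(city_id = "C9",
                                                        x = 1, y = 2)))
  expect_match(w, "degenerate", all = TRUE)
  expect_equal(c(s1$x_std, s1$y_std), c(0, 0)) # single-point city -> zeros
})

test_that("Central American countries pool to one level", {
  expect_equal(pool_central_america(c("BR", "SV", "NI", "PA", "CR", "GT", "MX")),
               c("BR", "CA", "CA", "CA", "CA", "CA", "MX"))
})

test_that("design assembly drops incomplete cases and standardises exposures", {
  td <- tiny_model_data(seed = 2)
  td$frame$available[3] <- NA # a provider error
  d <- build_availability_design(td$frame, td$units, "pct_sewer")
  expect_equal(nrow(d), nrow(td$frame) - 1L)
  expect_equal(mean(d$exposure), 0, tolerance = 1e-10)
  expect_equal(sd(d$exposure), 1, tolerance = 1e-10)
  expect_equal(mean(d$road_z), 0, tolerance = 1e-10)
  for (cid in unique(d$city_id)) {
    expect_equal(mean(d$x_std[d$city_id == cid]), 0, tolerance = 1e-9)
    expect_equal(sd(d$y_std[d$city_id == cid]), 1, tolerance = 1e-9)
  }
})

test_that("index exposures enter on their own scale, untransformed", {
  td <- tiny_model_data(seed = 3)
  d <- build_availability_design(td$frame, td$units, "index_without_poverty")
  idx <- ses_index_table(td$units)
  m <- match(unique(td$frame$subcity_id), idx$subcity_id)
  expect_equal(sort(unique(d$exposure)),
               sort(idx$index_without_poverty[m]))
})

test_that("zero-variance logistic fit matches the hand-rolled IRLS oracle", {
  td <- tiny_model_data(seed = 4)
  d <- build_availability_design(td$frame, td$units, "pct_piped_water")
  fit <- fit_availability_model(d, random = "none")
  X <- stats::model.matrix(~ exposure + road_z + area_z + country, data = d)
  orc <- oracle_logistic(X, d$available)
  expect_equal(unname(fit$b), unname(orc$coef[2]), tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(orc$se[2]), tolerance = 1e-4)
  expect_equal(unname(fit$odds_ratio), unname(exp(orc$coef[2])), tolerance = 1e-4)
})

test_that("zero-variance linear fit matches the normal-equation OLS oracle", {
  td <- tiny_model_data(seed = 5)
  cc <- td$frame[!is.na(td$frame$available), ]
  summ <- summarize_units(cc, "subcity_id")
  d <- build_subcity_design(summ, td$units, "mean_age_months", "pct_labor")
  fit <- fit_subcity_model(d, random = "none")
  X <- stats::model.matrix(~ exposure + area_z + country, data = d)
  orc <- oracle_ols(X, d$outcome)
  expect_equal(unname(fit$b), unname(orc$coef[2]), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(orc$se[2]), tolerance = 1e-8)
})

test_that("an exact linear outcome is recovered to numerical precision", {
  td <- tiny_model_data(seed = 6)
  cc <- td$frame[!is.na(td$frame$available), ]
  summ <- summarize_units(cc, "subcity_id")
  d <- build_subcity_design(summ, td$units, "mean_age_months", "pct_sewer")
  d$outcome <- 40 - 2.5 * d$exposure # noiseless truth
  fit <- suppressWarnings(fit_subcity_model(d, random = "none"))
  expect_equal(unname(fit$b), -2.5, tolerance = 1e-8)
})

test_that("single-class outcomes are flagged as separation", {
  td <- tiny_model_data(seed = 7)
  td$frame$available <- TRUE
  d <- build_availability_design(td$frame, td$units, "pct_sewer")
  expect_error(fit_availability_model(d), "separation")
})

test_that("rescaling a raw exposure leaves its Z-scored coefficient unchanged", {
  td <- tiny_model_data(seed = 8)
  d1 <- build_availability_design(td$frame, td$units, "pct_secondary_edu")
  td$units$pct_secondary_edu <- td$units$pct_secondary_edu * 37.5
  d2 <- build_availability_design(td$frame, td$units, "pct_secondary_edu")
  f1 <- fit_availability_model(d1, random = "none")
  f2 <- fit_availability_model(d2, random = "none")
  expect_equal(unname(f1$b), unname(f2$b), tolerance = 1e-6)
})

test_that("the mixed logistic fit returns sane per-SD estimates", {
  td <- tiny_model_data(seed = 9, beta_ses = 0.5)
  d <- build_availability_design(td$frame, td$units, "ses_truth")
  fit <- fit_availability_model(d)
  expect_true(fit$converged)
  expect_gt(fit$se, 0)
  expect_equal(unname(fit$odds_ratio), exp(unname(fit$b)))
  expect_true(abs(fit$b - 0.5) < 4 * fit$se)
  expect_named(fit$varcomp, c("city_id.(Intercept)", "city_id.1.x_std",
                              "city_id.2.y_std"))
})

test_that("the mixed linear fit needs enough units and >= 2 cities", {
  td <- tiny_model_data(seed = 10)
  cc <- td$frame[!is.na(td$frame$available), ]
  summ <- summarize_units(cc, "subcity_id")
  d <- build_subcity_design(summ, td$units, "sd_age_months", "pct_labor")
  fit <- fit_subcity_model(d)
  expect_true(fit$converged)
  expect_gt(fit$se, 0)
  expect_error(fit_subcity_model(d[1:7, ][d$city_id[1:7] == d$city_id[1], ]),
               ".")
})

test_that("the battery enumerates exposures x outcomes and survives failures", {
  td <- tiny_model_data(seed = 11)
  td$units$pct_labor <- 55 # constant covariate -> zscore error in one cell
  res <- run_model_battery(td$frame, td$units,
                           exposures = c("pct_sewer", "pct_labor", "pop_density"),
                           outcomes = c("availability", "mean_age", "sd_age"),
                           random_logistic = "intercept")
  expect_equal(nrow(res), 9L)
  failed <- res[res$exposure == "pct_labor", ]
  expect_true(all(!is.na(failed$error)))
  okrows <- res[res$exposure != "pct_labor", ]
  expect_true(all(is.na(okrows$error)))
  expect_true(all(is.finite(okrows$b)))
  # odds ratios only for the logistic family
  expect_true(all(is.finite(okrows$OR[okrows$outcome == "availability"])))
  expect_true(all(is.na(okrows$OR[okrows$outcome != "availability"])))
})

test_that("battery results are invariant to input row order", {
  td <- tiny_model_data(seed = 12)
  r1 <- run_model_battery(td$frame, td$units, exposures = "pct_sewer",
                          outcomes = c("availability", "mean_age"),
                          random_logistic = "none", random_linear = "none")
  perm <- sample(nrow(td$frame))
  r2 <- run_model_battery(td$frame[perm, ], td$units, exposures = "pct_sewer",
                          outcomes = c("availability", "mean_age"),
                          random_logistic = "none", random_linear = "none")
  expect_equal(r1$b, r2$b, tolerance = 1e-8)
  expect_equal(r1$SE, r2$SE, tolerance = 1e-8)
})

test_that("per-country strata fit within each pooled country level", {
  td <- tiny_model_data(seed = 13, n_cities = 6, units_per_city = 4)
  res <- run_model_battery(td$frame, td$units, exposures = "pct_sewer",
                           outcomes = "availability",
                           strata = "per-country",
                           random_logistic = "none")
  expect_setequal(res$stratum, unique(pool_central_america(td$units$country)))
})
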