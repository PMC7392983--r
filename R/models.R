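# Association models: point-level mixed-effect logistic regression for
# imagery availability (city random intercept + random slopes on the city's
# Z-standardised X/Y coordinates) and subcity-level mixed-effect linear
# regression for image age and image-age variance (city random intercept).
# Fitting is delegated to lme4 (Laplace approximation for the logistic
# marginal likelihood, REML for the linear models); this module owns design
# assembly, per-model standardisation, Central-America pooling, and result
# extraction. The zero-random-effect degenerate path uses plain glm/lm.

CENTRAL_AMERICA <- c("SV", "NI", "PA", "CR", "GT")

#' Pool Central American countries into one level
#'
#' @param country character vector of ISO-style country codes.
#' @return character vector with El Salvador, Nicaragua, Panama, Costa
#'   Rica, and Guatemala recoded to `"CA"`.
#' @export
pool_central_america <- function(country) {
  ifelse(country %in% CENTRAL_AMERICA, "CA", country)
}

#' Z-standardise point coordinates to each city's centre of mass
#'
#' Per city and per axis: subtract the unweighted mean of the sampled
#' points' coordinates and divide by their sample SD. A city with a single
#' point (or zero spread on an axis) gets 0 on that axis with a warning.
#'
#' @param points data.frame with columns city_id, x, y.
#' @return `points` with `x_std` and `y_std` columns added.
#' @export
standardize_xy <- function(points) {
  points$x_std <- NA_real_
  points$y_std <- NA_real_
  for (cid in unique(points$city_id)) {
    idx <- which(points$city_id == cid)
    for (axis in c("x", "y")) {
      v <- points[[axis]][idx]
      s <- if (length(v) >= 2L) stats::sd(v) else 0
      if (!is.finite(s) || s == 0) {
        warning(sprintf("city %s: degenerate %s spread; coordinates set to 0",
                        cid, axis))
        points[[paste0(axis, "_std")]][idx] <- 0
      } else {
        points[[paste0(axis, "_std")]][idx] <- (v - mean(v)) / s
      }
    }
  }
  points
}

# exposures that are already index scales and must not be re-standardised
.INDEX_EXPOSURES <- c("index_without_poverty", "index_with_poverty")

# Merge unit-level columns (exposure, area, country) onto the point frame
# and attach the index columns when requested.
.unit_lookup <- function(units, exposure) {
  df <- units
  if (exposure %in% .INDEX_EXPOSURES) {
    idx <- ses_index_table(units)
    df <- merge(df, idx, by = "subcity_id", all.x = TRUE)
  }
  if (!exposure %in% names(df)) {
    stop("exposure '", exposure, "' not found among unit covariates",
         call. = FALSE)
  }
  df
}

#' Assemble the point-level availability design
#'
#' Complete-case rows only: ERROR points, points in no subcity unit, and
#' points whose unit lacks the exposure are dropped. The exposure, the road
#' length in the buffer, and the unit area are Z-scored across the retained
#' rows (index exposures are used on their own scale, untransformed);
#' coordinates are Z-standardised per city to the centre of mass of the
#' city's sampled points; Central American countries are pooled.
#'
#' @param frame audited point frame (from [audit_points()]).
#' @param units data.frame of subcity units (covariates + area_km2 +
#'   country + city_id).
#' @param exposure name of the unit covariate or index used as exposure.
#' @return design data.frame with attributes `exposure` and `n`.
#' @export
build_availability_design <- function(frame, units, exposure) {
  udf <- .unit_lookup(units, exposure)
  cols <- c("subcity_id", "area_km2", "country", exposure)
  m <- merge(frame, udf[, cols], by = "subcity_id")
  keep <- !is.na(m$available) & !is.na(m[[exposure]]) & !is.na(m$road_length_m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete-case rows for availability design",
                          call. = FALSE)
  d <- data.frame(
    available = as.integer(m$available),
    exposure = if (exposure %in% .INDEX_EXPOSURES) m[[exposure]]
               else zscore(m[[exposure]]),
    road_z = zscore(m$road_length_m),
    area_z = if (length(unique(m$area_km2)) > 1L) zscore(m$area_km2) else 0,
    country = factor(pool_central_america(m$country)),
    city_id = m$city_id,
    x = m$x, y = m$y,
    stringsAsFactors = FALSE)
  d <- standardize_xy(d)
  attr(d, "exposure") <- exposure
  attr(d, "n") <- nrow(d)
  d
}

#' Assemble the subcity-level design for age / age-variance models
#'
#' One row per subcity unit with a defined outcome (units with no available
#' imagery have no mean age; units with fewer than two have no age SD —
#' complete-case sets are outcome specific). Exposure and area are Z-scored
#' across the retained units; index exposures stay on their own scale.
#'
#' @param unit_summary output of [summarize_units()] at the subcity level.
#' @param units subcity unit covariate table.
#' @param outcome `"mean_age_months"` or `"sd_age_months"`.
#' @param exposure unit covariate or index name.
#' @return design data.frame with attributes `exposure`, `outcome`, `n`.
#' @export
build_subcity_design <- function(unit_summary, units, outcome, exposure) {
  stopifnot(outcome %in% c("mean_age_months", "sd_age_months"))
  udf <- .unit_lookup(units, exposure)
  m <- merge(unit_summary, udf, by.x = "unit_id", by.y = "subcity_id")
  keep <- !is.na(m[[outcome]]) & !is.na(m[[exposure]])
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 3L) stop("too few subcity units with a defined outcome",
                         call. = FALSE)
  d <- data.frame(
    outcome = m[[outcome]],
    exposure = if (exposure %in% .INDEX_EXPOSURES) m[[exposure]]
               else zscore(m[[exposure]]),
    area_z = if (length(unique(m$area_km2)) > 1L) zscore(m$area_km2) else 0,
    country = factor(pool_central_america(m$country)),
    city_id = m$city_id,
    stringsAsFactors = FALSE)
  attr(d, "exposure") <- exposure
  attr(d, "outcome") <- outcome
  attr(d, "n") <- nrow(d)
  d
}

.fixed_rhs <- function(design) {
  rhs <- "exposure"
  if ("road_z" %in% names(design)) rhs <- c(rhs, "road_z")
  if (length(unique(design$area_z)) > 1L) rhs <- c(rhs, "area_z")
  if (nlevels(droplevels(design$country)) > 1L) rhs <- c(rhs, "country")
  paste(rhs, collapse = " + ")
}

.model_result <- function(exposure, outcome, n, b, se, p, odds_ratio = NA_real_,
                          varcomp = NULL, converged = TRUE, model = NULL) {
  structure(list(exposure = exposure, outcome = outcome, n = n,
                 b = b, se = se, p = p, odds_ratio = odds_ratio,
                 varcomp = varcomp, converged = converged, model = model),
            class = "model_result")
}

#' @exportS3Method base::print
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s ~ %s  n=%d  b=%.4f  se=%.4f  p=%.3g%s%s\n",
              x$outcome, x$exposure, x$n, x$b, x$se, x$p,
              if (!is.na(x$odds_ratio)) sprintf("  OR=%.4f", x$odds_ratio) else "",
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

.varcomp_vector <- function(fit) {
  vc <- lme4::VarCorr(fit)
  out <- c()
  for (g in names(vc)) {
    v <- diag(vc[[g]])
    names(v) <- paste(g, names(v), sep = ".")
    out <- c(out, v)
  }
  out
}

#' Fit the mixed-effect logistic availability model
#'
#' Binary imagery availability on the Z-scored exposure, controlling for
#' Z-scored road length in the buffer, country (Central America pooled),
#' and Z-scored subcity area, with city-grouped random effects on the
#' intercept and on the per-city standardised X/Y coordinates (independent
#' variance components). The marginal likelihood is integrated by the
#' Laplace approximation (`lme4::glmer`, nAGQ = 1). The reported odds
#' ratio is per SD of the exposure.
#'
#' @param design from [build_availability_design()].
#' @param random `"full"` (intercept + spatial slopes, the default),
#'   `"slopes"` (spatial slopes only), `"intercept"`, or `"none"`
#'   (plain logistic regression, the degenerate zero-variance limit).
#' @return a `model_result`.
#' @export
fit_availability_model <- function(design,
                                   random = c("full", "slopes", "intercept",
                                              "none")) {
  random <- match.arg(random)
  y <- design$available
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class: complete separation", call. = FALSE)
  }
  n_cities <- length(unique(design$city_id))
  if (random != "none" && n_cities < 2L) {
    stop("mixed model needs >= 2 cities", call. = FALSE)
  }
  fx <- .fixed_rhs(design)
  if (random == "none") {
    fit <- stats::glm(stats::as.formula(paste("available ~", fx)),
                      family = stats::binomial(), data = design)
    cf <- summary(fit)$coefficients["exposure", ]
    return(.model_result(attr(design, "exposure") %||% "exposure",
                         "availability", nrow(design),
                         cf[1L], cf[2L], cf[4L], exp(cf[1L]),
                         varcomp = c(), converged = fit$converged, model = fit))
  }
  re <- switch(random,
    full = "(1 | city_id) + (0 + x_std | city_id) + (0 + y_std | city_id)",
    slopes = "(0 + x_std | city_id) + (0 + y_std | city_id)",
    intercept = "(1 | city_id)")
  form <- stats::as.formula(paste("available ~", fx, "+", re))
  warned <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, family = stats::binomial(), data = design, nAGQ = 1L,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients["exposure", ]
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    !any(grepl("failed to converge|unidentifiable", warned))
  .model_result(attr(design, "exposure") %||% "exposure", "availability",
                nrow(design), cf[1L], cf[2L], cf[4L], exp(cf[1L]),
                varcomp = .varcomp_vector(fit), converged = conv, model = fit)
}

#' Fit the mixed-effect linear subcity model
#'
#' Subcity mean image age or image-age SD on the Z-scored exposure,
#' controlling for country and Z-scored subcity area, with a city random
#' intercept, fitted by REML (`lme4::lmer`). The coefficient is months per
#' SD of the exposure; its p-value uses the large-sample normal
#' approximation of b / se.
#'
#' @param design from [build_subcity_design()].
#' @param random `"intercept"` (default) or `"none"` (ordinary least
#'   squares, the degenerate zero-variance limit).
#' @return a `model_result`.
#' @export
fit_subcity_model <- function(design, random = c("intercept", "none")) {
  random <- match.arg(random)
  fx <- .fixed_rhs(design)
  p_fixed <- length(attr(stats::terms(
    stats::as.formula(paste("outcome ~", fx))), "term.labels")) + 1L
  if (nrow(design) <= p_fixed) {
    stop("fewer subcity units than fixed-effect parameters", call. = FALSE)
  }
  if (random == "none") {
    fit <- stats::lm(stats::as.formula(paste("outcome ~", fx)), data = design)
    cf <- summary(fit)$coefficients["exposure", ]
    b <- cf[1L]; se <- cf[2L]
    return(.model_result(attr(design, "exposure") %||% "exposure",
                         attr(design, "outcome") %||% "outcome",
                         nrow(design), b, se, 2 * stats::pnorm(-abs(b / se)),
                         varcomp = c(), converged = TRUE, model = fit))
  }
  if (length(unique(design$city_id)) < 2L) {
    stop("mixed model needs >= 2 cities", call. = FALSE)
  }
  form <- stats::as.formula(paste("outcome ~", fx, "+ (1 | city_id)"))
  warned <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = design, REML = TRUE),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients["exposure", ]
  b <- cf[1L]; se <- cf[2L]
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    !any(grepl("failed to converge", warned))
  .model_result(attr(design, "exposure") %||% "exposure",
                attr(design, "outcome") %||% "outcome",
                nrow(design), b, se, 2 * stats::pnorm(-abs(b / se)),
                varcomp = .varcomp_vector(fit), converged = conv, model = fit)
}

#' Run the full exposure x outcome model battery
#'
#' One model per exposure per outcome (per stratum): mixed logistic for
#' availability at the point level, mixed linear for mean age and age SD at
#' the subcity level. A failing cell is recorded with its error message and
#' does not abort the battery.
#'
#' @param frame audited point frame.
#' @param units subcity unit covariate table.
#' @param exposures character vector of covariate / index names.
#' @param outcomes subset of c("availability", "mean_age", "sd_age").
#' @param strata `"all"` or `"per-country"` (countries pooled as in the
#'   fixed effects).
#' @param random_logistic,random_linear random-effect structures passed to
#'   the fitters.
#' @return data.frame: outcome, exposure, stratum, n, b, OR, SE, p,
#'   converged, error.
#' @export
run_model_battery <- function(frame, units,
                              exposures = c(SES_CORE_COVARIATES,
                                            SES_POVERTY_COVARIATE,
                                            .INDEX_EXPOSURES),
                              outcomes = c("availability", "mean_age",
                                           "sd_age"),
                              strata = c("all", "per-country"),
                              random_logistic = "full",
                              random_linear = "intercept") {
  strata <- match.arg(strata)
  outcome_col <- c(availability = "availability",
                   mean_age = "mean_age_months", sd_age = "sd_age_months")
  stratum_sets <- if (strata == "all") list(all = units)
  else split(units, pool_central_america(units$country))

  rows <- list()
  for (sname in names(stratum_sets)) {
    su <- stratum_sets[[sname]]
    sf <- frame[frame$subcity_id %in% su$subcity_id, , drop = FALSE]
    cc <- sf[!is.na(sf$available), , drop = FALSE]
    summ <- if (nrow(cc) > 0L) summarize_units(cc, by = "subcity_id") else NULL
    for (outc in outcomes) {
      for (ex in exposures) {
        res <- tryCatch({
          if (outc == "availability") {
            d <- build_availability_design(sf, su, ex)
            fit_availability_model(d, random = random_logistic)
          } else {
            d <- build_subcity_design(summ, su, outcome_col[[outc]], ex)
            fit_subcity_model(d, random = random_linear)
          }
        }, error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(outcome = outc, exposure = ex, stratum = sname,
                     n = NA_integer_, b = NA_real_, OR = NA_real_,
                     SE = NA_real_, p = NA_real_, converged = FALSE,
                     error = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          data.frame(outcome = outc, exposure = ex, stratum = sname,
                     n = res$n, b = unname(res$b), OR = unname(res$odds_ratio),
                     SE = unname(res$se), p = unname(res$p),
                     converged = res$converged, error = NA_character_,
                     stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
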