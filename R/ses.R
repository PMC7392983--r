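# Socioeconomic covariate standardisation and the combined Z-score indices.

# the six core covariates, plus poverty for the seven-variable index
SES_CORE_COVARIATES <- c("pop_density", "pct_piped_water", "pct_sewer",
                         "pct_durable_walls", "pct_labor", "pct_secondary_edu")
SES_POVERTY_COVARIATE <- "pct_above_poverty"

#' Z-score standardisation
#'
#' Centres and scales to sample mean 0 and sample SD 1 (n - 1 denominator).
#' Missing entries are excluded from the mean/SD and propagate as missing.
#'
#' @param values numeric vector with >= 2 observed values and nonzero spread.
#' @return standardised numeric vector of the same length.
#' @export
zscore <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L) {
    stop("zscore needs at least 2 observed values", call. = FALSE)
  }
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) {
    stop("degenerate spread: cannot Z-score a constant vector", call. = FALSE)
  }
  (values - mean(obs)) / s
}

#' Combined socioeconomic index from subcity covariates
#'
#' Z-scores each covariate across the supplied analysis set and sums the
#' Z-scores per unit (unweighted). The six-variable index uses population
#' density, piped water, sewer connection, durable walls, labour
#' participation, and secondary education; the seven-variable index adds
#' the share of households above the poverty line. Units missing any
#' required covariate are excluded (listwise) and reported in the
#' `excluded` attribute. Higher index = better socioeconomic conditions.
#'
#' @param units data.frame of subcity units with the covariate columns and
#'   `subcity_id`.
#' @param include_poverty include the poverty covariate (seven-variable
#'   index)?
#' @return data.frame: subcity_id, index (one row per complete-case unit),
#'   with attribute `excluded` listing dropped subcity_ids.
#' @export
combined_index <- function(units, include_poverty = FALSE) {
  covs <- SES_CORE_COVARIATES
  if (include_poverty) covs <- c(covs, SES_POVERTY_COVARIATE)
  missing_cols <- setdiff(covs, names(units))
  if (length(missing_cols)) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(units[, covs, drop = FALSE])
  excluded <- units$subcity_id[!complete]
  use <- units[complete, , drop = FALSE]
  if (nrow(use) < 2L) {
    stop("fewer than 2 complete-case units; cannot standardise", call. = FALSE)
  }
  z <- vapply(covs, function(v) zscore(use[[v]]), numeric(nrow(use)))
  out <- data.frame(subcity_id = use$subcity_id,
                    index = rowSums(z),
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Both combined indices side by side
#'
#' @param units data.frame of subcity units.
#' @return data.frame: subcity_id, index_without_poverty,
#'   index_with_poverty (NA where poverty is missing).
#' @export
ses_index_table <- function(units) {
  no_pov <- combined_index(units, include_poverty = FALSE)
  out <- data.frame(subcity_id = no_pov$subcity_id,
                    index_without_poverty = no_pov$index,
                    index_with_poverty = NA_real_,
                    stringsAsFactors = FALSE)
  has_pov <- SES_POVERTY_COVARIATE %in% names(units) &&
    sum(!is.na(units[[SES_POVERTY_COVARIATE]])) >= 2L
  if (has_pov) {
    with_pov <- tryCatch(combined_index(units, include_poverty = TRUE),
                         error = function(e) NULL)
    if (!is.null(with_pov)) {
      m <- match(out$subcity_id, with_pov$subcity_id)
      out$index_with_poverty <- with_pov$index[m]
    }
  }
  out
}
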