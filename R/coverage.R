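# Coverage outcomes: imagery availability, image age (months before the
# study reference date), and image-age variance, aggregated at subcity,
# city, and country levels.

#' Image age in whole months before a reference date
#'
#' @param capture_year,capture_month capture date (month 1-12).
#' @param ref_year,ref_month reference date, default April 2019.
#' @return integer months, `(ref_year - capture_year) * 12 +
#'   (ref_month - capture_month)`, always >= 0.
#' @export
image_age_months <- function(capture_year, capture_month,
                             ref_year = 2019, ref_month = 4) {
  if (any(is.na(capture_year)) || any(is.na(capture_month))) {
    stop("missing capture date", call. = FALSE)
  }
  if (any(capture_month < 1 | capture_month > 12) ||
      any(ref_month < 1 | ref_month > 12)) {
    stop("months must be in 1..12", call. = FALSE)
  }
  age <- (ref_year - capture_year) * 12L + (ref_month - capture_month)
  if (any(age < 0)) {
    stop("capture date after the reference date", call. = FALSE)
  }
  as.integer(age)
}

#' Summarise coverage for groups of audited points
#'
#' Availability is the percentage of points with imagery; mean and SD of
#' image age are computed over available points only, with the sample
#' (n - 1) SD. The mean needs >= 1 available point and the SD >= 2;
#' otherwise they are `NA`. ERROR points must already be removed
#' (complete-case contract).
#'
#' @param frame audited point frame (columns `available`, `age_months`, and
#'   the grouping column).
#' @param by name of the grouping column (`"subcity_id"`, `"city_id"`, or
#'   `"country"`).
#' @return data.frame: unit_id, n_points, n_available, availability_pct,
#'   mean_age_months, sd_age_months. Values at full precision.
#' @export
summarize_units <- function(frame, by = "subcity_id") {
  if (!by %in% names(frame)) stop("no column '", by, "' in frame", call. = FALSE)
  if (nrow(frame) == 0L) stop("cannot summarise an empty frame", call. = FALSE)
  if (any(is.na(frame$available))) {
    stop("frame contains ERROR/NA availability; drop them first (complete case)",
         call. = FALSE)
  }
  groups <- split(seq_len(nrow(frame)), frame[[by]])
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    avail <- frame$available[idx]
    ages <- frame$age_months[idx][avail]
    data.frame(
      unit_id = g,
      n_points = length(idx),
      n_available = sum(avail),
      availability_pct = 100 * sum(avail) / length(idx),
      mean_age_months = if (length(ages) >= 1L) mean(ages) else NA_real_,
      sd_age_months = if (length(ages) >= 2L) stats::sd(ages) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$unit_id), , drop = FALSE]
}

#' Overall availability report for an audited frame
#'
#' Counts and percentages of OK / ZERO_RESULTS / ERROR outcomes. Counts are
#' exact; percentages are kept at full precision with display-rounded
#' companions (one decimal for availability, three for the error rate,
#' mirroring how such audits are conventionally reported).
#'
#' @param frame audited point frame with a `status` column.
#' @return list with n_audited, n_ok, n_zero_results, n_error, pct_ok,
#'   pct_zero_results, pct_error and their `*_rounded` versions.
#' @export
availability_report <- function(frame) {
  st <- frame$status
  n <- length(st)
  n_ok <- sum(st == "OK")
  n_zero <- sum(st == "ZERO_RESULTS")
  n_err <- sum(st == "ERROR")
  stopifnot(n_ok + n_zero + n_err == n)
  pct <- function(k) if (n == 0L) 0 else 100 * k / n
  list(n_audited = n, n_ok = n_ok, n_zero_results = n_zero, n_error = n_err,
       pct_ok = pct(n_ok), pct_zero_results = pct(n_zero),
       pct_error = pct(n_err),
       pct_ok_rounded = round(pct(n_ok), 1),
       pct_zero_results_rounded = round(pct(n_zero), 1),
       pct_error_rounded = round(pct(n_err), 3))
}
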