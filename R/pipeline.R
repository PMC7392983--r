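# Pipeline orchestration: each stage reads the previous stage's flat
# artifacts (GeoJSON / CSV) from a run directory and writes its own, so a
# run is a pure function of (inputs, config, seed) and every intermediate
# is inspectable by external tools. A manifest records input hashes, the
# seed, and the resolved configuration.

#' Build a pipeline run configuration
#'
#' Defaults reproduce the audit's settings: 500-m sampling lattice, 100-m
#' buffer and metadata radius, April 2019 reference date.
#'
#' @param out_dir run directory for stage artifacts.
#' @param spacing_m lattice spacing (meters).
#' @param radius_m buffer / metadata search radius (meters).
#' @param ref_year,ref_month image-age reference date.
#' @param seed integer seed for stages that draw random numbers.
#' @param n_cities cities for the `simulate` stage.
#' @param strata `"all"` or `"per-country"` for the model battery.
#' @param random_logistic,random_linear random-effect structures.
#' @param exposures exposures for the model battery.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       spacing_m = 500, radius_m = 100,
                       ref_year = 2019, ref_month = 4,
                       seed = 1L, n_cities = 8L,
                       strata = "all",
                       random_logistic = "full",
                       random_linear = "intercept",
                       exposures = c(SES_CORE_COVARIATES,
                                     SES_POVERTY_COVARIATE,
                                     "index_without_poverty",
                                     "index_with_poverty")) {
  structure(list(out_dir = out_dir, spacing_m = spacing_m,
                 radius_m = radius_m, ref_year = ref_year,
                 ref_month = ref_month, seed = as.integer(seed),
                 n_cities = as.integer(n_cities), strata = strata,
                 random_logistic = random_logistic,
                 random_linear = random_linear, exposures = exposures),
            class = "run_config")
}

.artifact <- function(config, name) file.path(config$out_dir, name)

.require_artifact <- function(config, name, produced_by) {
  p <- .artifact(config, name)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s'; run the '%s' stage first",
                 name, produced_by), call. = FALSE)
  }
  p
}

.write_manifest <- function(config, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("streetcover")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(manifest,
                       .artifact(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

.stage_simulate <- function(config) {
  study <- simulate_study(n_cities = config$n_cities, seed = config$seed)
  # write geographic (lon/lat) artifacts so the sample stage exercises the
  # same projection path as real data
  to_ll <- function(m, crs) {
    ll <- aeqd_inverse(m[, 1L], m[, 2L], crs$lon0, crs$lat0, crs$radius_m)
    cbind(ll$lon, ll$lat)
  }
  bounds <- lapply(study$cities, function(ct) {
    crs <- ct$boundary$crs
    list(city_id = ct$boundary$city_id, country = ct$boundary$country,
         geom = lapply(ct$boundary$geom, function(p) lapply(p, to_ll, crs = crs)))
  })
  units <- unlist(lapply(study$cities, function(ct) {
    crs <- ct$boundary$crs
    lapply(ct$units, function(u) {
      u$geom <- lapply(u$geom, function(p) lapply(p, to_ll, crs = crs))
      u
    })
  }), recursive = FALSE)
  segs <- list(); seg_city <- character(0); panos <- list()
  for (ct in study$cities) {
    crs <- ct$boundary$crs
    segs <- c(segs, lapply(ct$roads$segments, to_ll, crs = crs))
    seg_city <- c(seg_city, rep(ct$boundary$city_id,
                                length(ct$roads$segments)))
    p <- ct$panoramas
    ll <- aeqd_inverse(p$x, p$y, crs$lon0, crs$lat0, crs$radius_m)
    p$lon <- ll$lon; p$lat <- ll$lat
    p$city_id <- ct$boundary$city_id
    panos[[length(panos) + 1L]] <-
      p[, c("pano_id", "city_id", "subcity_id", "lon", "lat",
            "capture_year", "capture_month")]
  }
  write_polygons_geojson(bounds, .artifact(config, "boundaries.geojson"),
                         c("city_id", "country"))
  write_polygons_geojson(units, .artifact(config, "units.geojson"),
                         c("subcity_id", "city_id", "country", "area_km2"))
  write_roads_geojson(segs, .artifact(config, "roads.geojson"), seg_city)
  utils::write.csv(do.call(rbind, panos),
                   .artifact(config, "panoramas.csv"), row.names = FALSE)
  utils::write.csv(study$covariates, .artifact(config, "covariates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            config = unclass(study$truth$config),
                            sub_seeds = study$truth$sub_seeds),
                       .artifact(config, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  .write_manifest(config, "simulate", character(0),
                  vapply(c("boundaries.geojson", "units.geojson",
                           "roads.geojson", "panoramas.csv",
                           "covariates.csv"),
                         function(f) .artifact(config, f), character(1)))
  invisible(TRUE)
}

.stage_sample <- function(config) {
  bpath <- .require_artifact(config, "boundaries.geojson", "simulate")
  rpath <- .require_artifact(config, "roads.geojson", "simulate")
  upath <- .require_artifact(config, "units.geojson", "simulate")
  bounds <- read_boundaries_geojson(bpath)
  roads <- read_roads_geojson(rpath)
  units <- read_units_geojson(upath)
  frames <- list()
  for (b in bounds) {
    segs <- roads$segments[!is.na(roads$city_id) & roads$city_id == b$city_id]
    if (length(segs) == 0L) segs <- roads$segments[is.na(roads$city_id)]
    uu <- Filter(function(u) identical(u$city_id, b$city_id), units)
    proj <- project_city(b, segs, uu)
    frames[[length(frames) + 1L]] <-
      build_sample_frame(proj$boundary, proj$roads, proj$units,
                         spacing_m = config$spacing_m,
                         radius_m = config$radius_m)
  }
  frame <- do.call(rbind, frames)
  out <- .artifact(config, "sample_frame.csv")
  utils::write.csv(frame, out, row.names = FALSE)
  message(sprintf("sample: %d points, %d eligible (%.1f%%)",
                  nrow(frame), sum(frame$eligible),
                  100 * mean(frame$eligible)))
  .write_manifest(config, "sample", c(bpath, rpath, upath), out)
  invisible(TRUE)
}

.stage_audit <- function(config) {
  spath <- .require_artifact(config, "sample_frame.csv", "sample")
  ppath <- .require_artifact(config, "panoramas.csv", "simulate")
  bpath <- .require_artifact(config, "boundaries.geojson", "simulate")
  frame <- utils::read.csv(spath, stringsAsFactors = FALSE)
  panos <- utils::read.csv(ppath, stringsAsFactors = FALSE)
  bounds <- read_boundaries_geojson(bpath)
  audited <- list()
  for (b in bounds) {
    el <- frame[frame$city_id == b$city_id & frame$eligible, , drop = FALSE]
    if (nrow(el) == 0L) next
    ctr <- geom_centroid(b$geom)
    pp <- panos[panos$city_id == b$city_id, , drop = FALSE]
    xy <- aeqd_forward(pp$lon, pp$lat, ctr[1L], ctr[2L])
    pp$x <- xy$x; pp$y <- xy$y
    provider <- synthetic_provider(pp)
    aud <- audit_points(el, provider, radius_m = config$radius_m,
                        ref_year = config$ref_year,
                        ref_month = config$ref_month)
    audited[[length(audited) + 1L]] <- aud$frame
  }
  out_frame <- do.call(rbind, audited)
  report <- availability_report(out_frame)
  opath <- .artifact(config, "audit.csv")
  utils::write.csv(out_frame, opath, row.names = FALSE)
  jsonlite::write_json(report, .artifact(config, "audit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("audit: %d OK (%.1f%%), %d ZERO_RESULTS, %d ERROR",
                  report$n_ok, report$pct_ok, report$n_zero_results,
                  report$n_error))
  .write_manifest(config, "audit", c(spath, ppath),
                  c(opath, .artifact(config, "audit_report.json")))
  invisible(TRUE)
}

.stage_aggregate <- function(config) {
  apath <- .require_artifact(config, "audit.csv", "audit")
  cpath <- .require_artifact(config, "covariates.csv", "simulate")
  frame <- utils::read.csv(apath, stringsAsFactors = FALSE)
  covs <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  cc <- frame[!is.na(frame$available), , drop = FALSE]
  cc$country <- covs$country[match(cc$subcity_id, covs$subcity_id)]
  outs <- character(0)
  for (lvl in c("subcity_id", "city_id", "country")) {
    summ <- summarize_units(cc[!is.na(cc[[lvl]]), , drop = FALSE], by = lvl)
    f <- .artifact(config, sprintf("coverage_%s.csv", sub("_id$", "", lvl)))
    utils::write.csv(summ, f, row.names = FALSE)
    outs <- c(outs, f)
  }
  .write_manifest(config, "aggregate", c(apath, cpath), outs)
  invisible(TRUE)
}

.stage_index <- function(config) {
  cpath <- .require_artifact(config, "covariates.csv", "simulate")
  covs <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  idx <- ses_index_table(covs)
  out <- .artifact(config, "ses_index.csv")
  utils::write.csv(idx, out, row.names = FALSE)
  .write_manifest(config, "index", cpath, out)
  invisible(TRUE)
}

.stage_model <- function(config) {
  apath <- .require_artifact(config, "audit.csv", "audit")
  cpath <- .require_artifact(config, "covariates.csv", "simulate")
  frame <- utils::read.csv(apath, stringsAsFactors = FALSE)
  covs <- utils::read.csv(cpath, stringsAsFactors = FALSE)
  res <- run_model_battery(frame, covs,
                           exposures = config$exposures,
                           strata = config$strata,
                           random_logistic = config$random_logistic,
                           random_linear = config$random_linear)
  out <- .artifact(config, "model_results.csv")
  utils::write.csv(res, out, row.names = FALSE)
  message(sprintf("model: %d cells, %d converged", nrow(res),
                  sum(res$converged, na.rm = TRUE)))
  .write_manifest(config, "model", c(apath, cpath), out)
  invisible(TRUE)
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (synthetic study -> GeoJSON/CSV inputs), `sample`
#' (lattice + eligibility), `audit` (imagery metadata), `aggregate`
#' (coverage summaries), `index` (combined SES indices), `model` (the
#' model battery), or `all` (chain everything). Each stage requires its
#' upstream artifacts and fails with a stage-dependency error otherwise.
#'
#' @param subcommand stage name.
#' @param config a `run_config`.
#' @return invisibly TRUE.
#' @export
cli_run <- function(subcommand = c("all", "simulate", "sample", "audit",
                                   "aggregate", "index", "model"),
                    config) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- switch(subcommand,
    all = c("simulate", "sample", "audit", "aggregate", "index", "model"),
    subcommand)
  for (s in stages) {
    switch(s,
      simulate = .stage_simulate(config),
      sample = .stage_sample(config),
      audit = .stage_audit(config),
      aggregate = .stage_aggregate(config),
      index = .stage_index(config),
      model = .stage_model(config))
  }
  invisible(TRUE)
}

#' Command-line entry point
#'
#' Parses `streetcover <subcommand> --out-dir DIR [--seed N] [--spacing-m X]
#' [--radius-m X] [--ref-date YYYY-MM] [--n-cities N] [--strata per-country]
#' [--config FILE]` and dispatches to [cli_run()]. A `--config` JSON file
#' supplies defaults that individual flags override.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: streetcover <simulate|sample|audit|aggregate|index|model|all> --out-dir DIR [options]")
    return(invisible(1L))
  }
  sub <- args[[1L]]
  opt <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  base <- list()
  if (!is.null(opt$config)) {
    base <- jsonlite::fromJSON(opt$config, simplifyVector = TRUE)
  }
  get_opt <- function(key, default) {
    if (!is.null(opt[[key]])) opt[[key]] else base[[key]] %||% default
  }
  ref <- strsplit(as.character(get_opt("ref-date", "2019-04")), "-")[[1L]]
  cfg <- run_config(
    out_dir = get_opt("out-dir", stop("--out-dir is required", call. = FALSE)),
    spacing_m = as.numeric(get_opt("spacing-m", 500)),
    radius_m = as.numeric(get_opt("radius-m", 100)),
    ref_year = as.integer(ref[1L]), ref_month = as.integer(ref[2L]),
    seed = as.integer(get_opt("seed", 1L)),
    n_cities = as.integer(get_opt("n-cities", 8L)),
    strata = as.character(get_opt("strata", "all")))
  status <- tryCatch({ cli_run(sub, cfg); 0L },
                     error = function(e) { message("error: ",
                                                   conditionMessage(e)); 1L })
  invisible(status)
}
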