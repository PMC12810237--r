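#' @title Config-driven pipeline runs
#' @description
#' `run_behavior()` chains tracking import, viability exclusions, endpoint
#' extraction, effect statistics and (optionally) reference-library
#' fingerprinting; `run_chemistry()` chains peak binning, retention
#' indexing, PLS retention modeling, plausibility filtering and composition
#' summaries. Both write their outputs plus a JSON manifest (package
#' version, seed, config hash, output list) sufficient to reproduce the run.
#' @name pipeline
NULL

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: config must be a list or YAML path")
  config
}

require_paths <- function(config, keys) {
  for (k in keys) {
    p <- config[[k]]
    if (is.null(p)) stop("config error: missing required path '", k, "'")
    if (!file.exists(p)) stop("config error: ", k, " file not found: ", p)
  }
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

write_manifest <- function(out_dir, stage, config, seed, outputs) {
  cfg_path <- file.path(out_dir, paste0(stage, "_config.json"))
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    stage = stage,
    package = "vamrscreen",
    version = as.character(utils::packageVersion("vamrscreen")),
    r_version = as.character(getRversion()),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    config_file = basename(cfg_path),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  mpath
}

#' Run the behavior arm of the pipeline
#'
#' @param config A list or YAML path with entries: `traces`, `plate_map`,
#'   `schedule` (paths; `statuses` optional), `out_dir`, and optional
#'   parameters `alpha` (0.05), `B` (1000), `seed` (1), `distance`,
#'   `linkage`, `library` (reference library path for fingerprinting).
#' @return Invisibly, a list with the endpoint matrix, effect table,
#'   fingerprints, optional cluster result, exclusion report, and the
#'   manifest path.
#' @export
run_behavior <- function(config) {
  config <- read_run_config(config)
  require_paths(config, c("traces", "plate_map", "schedule"))
  out_dir <- config$out_dir %||% stop("config error: missing out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  B <- config$B %||% 1000
  seed <- config$seed %||% 1L
  schedule <- with_stage("schedule", load_schedule(config$schedule))
  traces <- with_stage("behavior_io", read_traces(config$traces,
                                                  config$sampling_rate %||% 25))
  plate_map <- with_stage("behavior_io", read_plate_map(config$plate_map))
  statuses <- if (!is.null(config$statuses))
    with_stage("behavior_io", read_statuses(config$statuses)) else NULL
  excl <- with_stage("exclusions", apply_exclusions(traces, statuses))
  endpoints <- with_stage("endpoints",
                          compute_endpoint_matrix(excl$traces, schedule))
  eff <- with_stage("effect_stats",
                    effect_table(endpoints, plate_map, alpha = alpha, B = B,
                                 seed = seed))
  outputs <- character(0)
  p <- file.path(out_dir, "endpoint_matrix.csv")
  meta <- plate_map[match(endpoints$well, plate_map$well),
                    c("group", "treatment", "concentration", "unit")]
  write_endpoint_matrix(cbind(endpoints, meta), p); outputs <- c(outputs, p)
  p <- file.path(out_dir, "effect_table.csv")
  write_effect_table(eff, p); outputs <- c(outputs, p)
  p <- file.path(out_dir, "fingerprints.csv")
  write_fingerprints(eff, p); outputs <- c(outputs, p)
  p <- file.path(out_dir, "exclusion_report.csv")
  utils::write.csv(excl$report, p, row.names = FALSE); outputs <- c(outputs, p)
  clusters <- NULL
  if (!is.null(config$library)) {
    require_paths(config, "library")
    lib <- with_stage("fingerprinting", read_reference_library(config$library))
    clusters <- with_stage("fingerprinting",
      cluster_fingerprints(eff, lib,
                           distance = config$distance %||% "euclidean",
                           linkage = config$linkage %||% "ward.D2"))
    p <- file.path(out_dir, "cluster_assignments.csv")
    write_cluster_assignments(clusters, p); outputs <- c(outputs, p)
    p <- file.path(out_dir, "dendrogram.nwk")
    write_dendrogram_newick(clusters, p); outputs <- c(outputs, p)
    moa <- lapply(rownames(eff$fingerprints), function(g)
      moa_report(clusters, g))
    p <- file.path(out_dir, "moa_report.csv")
    utils::write.csv(do.call(rbind, lapply(moa, function(m)
      cbind(query = m$query, basis = m$basis, m$moa))), p, row.names = FALSE)
    outputs <- c(outputs, p)
  }
  manifest <- write_manifest(out_dir, "behavior", config, seed, outputs)
  invisible(list(endpoints = endpoints, effects = eff, clusters = clusters,
                 exclusions = excl, manifest = manifest, outputs = outputs))
}

#' Run the chemistry arm of the pipeline
#'
#' @param config A list or YAML path with entries: `peaks`, `ladder`
#'   (paths; `descriptors` and `calibration` optional), `out_dir`, and
#'   optional `seed` (1), `modulation_period` (6), filter thresholds
#'   `ri_tol` (200), `rt2_tol` (2), `score_min` (80). Without a descriptor
#'   table plus calibration set, retention prediction is skipped and every
#'   peak is rejected with reason `no_prediction`.
#' @return Invisibly, a list with binned peaks, the retention model (or
#'   NULL), retained/rejected identifications, composition summaries, and
#'   the manifest path.
#' @export
run_chemistry <- function(config) {
  config <- read_run_config(config)
  require_paths(config, c("peaks", "ladder"))
  out_dir <- config$out_dir %||% stop("config error: missing out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  peaks <- with_stage("gcxgc_io", read_peaks(config$peaks))
  ladder <- with_stage("gcxgc_io", read_alkane_ladder(config$ladder))
  binned <- with_stage("binning", bin_peaks(peaks))
  pk <- binned$peaks
  pk$ri_meas <- with_stage("retention_index",
                           retention_index(pk$rt1_min, ladder))
  model <- NULL
  if (!is.null(config$descriptors) && !is.null(config$calibration)) {
    require_paths(config, c("descriptors", "calibration"))
    desc <- with_stage("gcxgc_io", read_descriptors(config$descriptors))
    cal <- with_stage("gcxgc_io", {
      d <- utils::read.csv(config$calibration, stringsAsFactors = FALSE)
      miss <- setdiff(c(DESCRIPTOR_COLS, "ri", "rt2_s"), names(d))
      if (length(miss)) stop("calibration table missing columns: ",
                             paste(miss, collapse = ", "))
      d
    })
    model <- with_stage("retention_model",
      fit_retention_model(cal, n_train = config$n_train %||% 100,
                          n_test = config$n_test %||% 19, seed = seed))
    pred <- with_stage("retention_model",
      predict(model, desc[match(pk$cas, desc$cas), , drop = FALSE]))
    pk$ri_pred <- pred$ri_pred
    pk$rt2_pred <- pred$rt2_pred
  } else {
    pk$ri_pred <- NA_real_
    pk$rt2_pred <- NA_real_
  }
  filt <- with_stage("filter",
    filter_identifications(pk, ri_tol = config$ri_tol %||% 200,
                           rt2_tol = config$rt2_tol %||% 2,
                           score_min = config$score_min %||% 80))
  comp <- with_stage("composition", composition_summary(filt$retained))
  outputs <- character(0)
  p <- file.path(out_dir, "binned_peaks.csv")
  utils::write.csv(pk, p, row.names = FALSE); outputs <- c(outputs, p)
  p <- file.path(out_dir, "retained_identifications.csv")
  utils::write.csv(filt$retained, p, row.names = FALSE); outputs <- c(outputs, p)
  p <- file.path(out_dir, "rejected_identifications.csv")
  utils::write.csv(filt$rejected, p, row.names = FALSE); outputs <- c(outputs, p)
  if (length(comp$relative)) {
    p <- file.path(out_dir, "composition_relative.csv")
    utils::write.csv(comp$relative, p, row.names = FALSE); outputs <- c(outputs, p)
    p <- file.path(out_dir, "composition_classes.csv")
    utils::write.csv(comp$classes, p, row.names = FALSE); outputs <- c(outputs, p)
  }
  if (!is.null(model)) {
    p <- file.path(out_dir, "retention_model.json")
    write_retention_model(model, p); outputs <- c(outputs, p)
  }
  manifest <- write_manifest(out_dir, "chemistry", config, seed, outputs)
  invisible(list(binned = binned, model = model, retained = filt$retained,
                 rejected = filt$rejected, composition = comp,
                 manifest = manifest, outputs = outputs))
}
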