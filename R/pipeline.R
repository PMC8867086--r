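#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline stages (simulate, extract,
#' classify) with its default.  The configuration is serialised (with a
#' content hash) into every output for provenance, so re-running an
#' unchanged configuration reproduces identical numeric content.
#'
#' @param out_dir Output directory (created if missing).
#' @param timeseries_dir Directory of per-subject TSV time series; defaults
#'   to `file.path(out_dir, "timeseries")`.
#' @param partition_file Partition JSON; `NULL` means the bundled AAL
#'   six-network division.
#' @param labels_file Label TSV; defaults to `file.path(out_dir,
#'   "labels.tsv")`.
#' @param window Window parameters, `list(width, step)`.
#' @param fit Matrix-normal fit settings, `list(tol, max_iter, ridge)`.
#' @param selection Arguments for [selection_config()].
#' @param cohort Arguments for [cohort_spec()] (without `partition`).
#' @param baselines Extract static/dynamic baseline blocks too?
#' @param feature_set Tag filter for classification: `"all"` or any subset
#'   of the block tags (e.g. `"intra_low"` for an ablation run).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "hierfcn_out",
                       timeseries_dir = NULL, partition_file = NULL,
                       labels_file = NULL,
                       window = list(width = 60L, step = 4L),
                       fit = list(tol = 1e-6, max_iter = 100L, ridge = 1e-6),
                       selection = list(),
                       cohort = list(),
                       baselines = FALSE, feature_set = "all") {
  cfg <- list(
    out_dir = out_dir,
    timeseries_dir = timeseries_dir %||% file.path(out_dir, "timeseries"),
    partition_file = partition_file,
    labels_file = labels_file %||% file.path(out_dir, "labels.tsv"),
    window = utils::modifyList(list(width = 60L, step = 4L), window),
    fit = utils::modifyList(list(tol = 1e-6, max_iter = 100L, ridge = 1e-6), fit),
    selection = selection, cohort = cohort,
    baselines = isTRUE(baselines), feature_set = feature_set
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from a YAML file
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configurations")
  }
  do.call(run_config, yaml::read_yaml(path))
}

config_partition <- function(config, roi_names) {
  if (is.null(config$partition_file)) return(aal_subnetworks())
  if (is.null(roi_names)) {
    # no time series yet (simulate): take the ROI universe from the file
    raw <- jsonlite::read_json(config$partition_file, simplifyVector = TRUE)
    raw <- raw[!startsWith(names(raw), "_")]
    if (is.character(raw[[1]])) roi_names <- unname(unlist(raw))
  }
  load_partition(config$partition_file, roi_names)
}

write_manifest <- function(config, path, extra = list()) {
  obj <- c(list(config = unclass(config)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort described by `config$cohort` (against the
#' configured partition) and writes one TSV per subject, the label table,
#' the partition, the ground truth and a manifest into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the cohort list from [generate_cohort()].
#' @export
cmd_simulate <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(config$timeseries_dir, recursive = TRUE, showWarnings = FALSE)
  part <- config_partition(config, roi_names = NULL)
  spec <- do.call(cohort_spec, c(list(partition = part), config$cohort))
  cohort <- generate_cohort(spec)
  for (ts in cohort$timeseries) {
    write_timeseries(ts, file.path(config$timeseries_dir,
                                   paste0(ts$subject_id, ".tsv")))
  }
  write_labels(cohort$labels, config$labels_file)
  write_partition(part, file.path(config$out_dir, "partition.json"))
  gt <- cohort$ground_truth
  gt$state_sequence <- as.integer(gt$state_sequence)
  jsonlite::write_json(gt, file.path(config$out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  write_manifest(config, file.path(config$out_dir, "manifest.json"),
                 list(n_subjects = length(cohort$timeseries)))
  invisible(cohort)
}

#' Extract the fused feature table to disk
#'
#' Reads every subject in `config$timeseries_dir`, checks agreement with the
#' label table, runs [extract_features()] and writes `features.tsv`, the
#' provenance sidecar `features_provenance.json` and `dimension_report.tsv`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the feature table.
#' @export
cmd_extract <- function(config = run_config()) {
  files <- sort(list.files(config$timeseries_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) {
    abort(paste0("no time-series files in ", config$timeseries_dir),
          class = "hierfcn_validation")
  }
  subjects <- lapply(files, function(f) suppressWarnings(read_timeseries(f)))
  labels <- read_labels(config$labels_file)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  missing_lab <- setdiff(ids, labels$subject_id)
  missing_ts <- setdiff(labels$subject_id, ids)
  if (length(missing_lab) || length(missing_ts)) {
    abort(paste0("subject/label mismatch; unlabelled: ",
                 paste(missing_lab, collapse = ", "), "; missing series: ",
                 paste(missing_ts, collapse = ", ")),
          class = "hierfcn_validation")
  }
  part <- config_partition(config, roi_names = subjects[[1]]$roi_names)
  spec <- window_spec(config$window$width, config$window$step)
  feats <- extract_features(subjects, part, spec,
                            baselines = config$baselines,
                            tol = config$fit$tol,
                            max_iter = config$fit$max_iter,
                            ridge = config$fit$ridge)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(feats, file.path(config$out_dir, "features.tsv"))
  jsonlite::write_json(feature_provenance(feats),
                       file.path(config$out_dir, "features_provenance.json"),
                       dataframe = "rows", auto_unbox = TRUE, null = "null")
  readr::write_tsv(dimension_report(part, nrow(subjects[[1]]$values)),
                   file.path(config$out_dir, "dimension_report.tsv"))
  write_manifest(config, file.path(config$out_dir, "manifest_extract.json"),
                 list(n_subjects = length(subjects), n_features = ncol(feats) - 1L))
  invisible(feats)
}

#' Classify a feature table with nested cross-validation
#'
#' Loads the extracted features and labels, optionally restricts the
#' feature set to chosen block tags (ablation runs), runs [nested_cv()] and
#' writes `cv_result.json` (metrics, hyperparameters, selected features,
#' sub-network contributions, top edges).
#'
#' @param config A [run_config()].
#' @return Invisibly, the `cv_result`.
#' @export
cmd_classify <- function(config = run_config()) {
  fpath <- file.path(config$out_dir, "features.tsv")
  ppath <- file.path(config$out_dir, "features_provenance.json")
  if (!file.exists(fpath)) abort("run cmd_extract first: features.tsv missing",
                                 class = "hierfcn_validation")
  feats <- readr::read_tsv(fpath, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()))
  prov <- as_tibble(jsonlite::read_json(ppath, simplifyVector = TRUE))
  prov$network_2 <- as.character(prov$network_2)
  labels <- read_labels(config$labels_file)
  if (!identical(config$feature_set, "all")) {
    keep <- prov$feature[prov$tag %in% config$feature_set]
    if (length(keep) == 0) abort("feature_set matches no features",
                                 class = "hierfcn_validation")
    feats <- feats[, c("subject_id", keep)]
    prov <- prov[prov$tag %in% config$feature_set, ]
  }
  attr(feats, "provenance") <- prov
  cfg <- do.call(selection_config, config$selection)
  if (nrow(feats) < cfg$outer_folds) {
    abort("fewer subjects than outer folds", class = "hierfcn_validation")
  }
  res <- nested_cv(feats, labels, cfg)
  contrib <- tryCatch(contribution_trace(res), error = function(e) NULL)
  edges <- tryCatch(suppressWarnings(top_edges(res)), error = function(e) NULL)
  report <- list(config = unclass(config),
                 summary = res$summary, folds = res$folds,
                 selected = res$selected, contributions = contrib,
                 top_edges = edges)
  jsonlite::write_json(report, file.path(config$out_dir, "cv_result.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(res)
}
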