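#' Run the full co-occurrence rule pipeline
#'
#' Orchestrates the analysis end to end: cohort summary, candidate mining
#' (antecedent sizes up to `mining_config$max_lhs_size`), permutation-null
#' calibration, dynamic-threshold filtering, rule typing, and (when lineages
#' are supplied) validation against offspring virus compositions. A single
#' master seed in `calib_config` drives every stochastic stage.
#'
#' @param matrix a [pa_matrix()] or path to a wide-format CSV.
#' @param lineages optional list of [lineage()] objects or path to a lineage
#'   CSV.
#' @param mining_config a [mining_config()].
#' @param calib_config a [calibration_config()].
#' @param min_support,min_lift optional published-style global floors passed
#'   to [filter_significant_rules()].
#' @param out_dir optional directory; when given, all tabular/JSON artifacts
#'   are written via [export_report()].
#' @return a list of class `pipeline_bundle` with elements `summary`
#'   (cohort summary), `candidates`, `calibration`, `significant`
#'   (classified), `grouped`, `census`, `validation` (or `NULL`), and
#'   `counts` (stage bookkeeping including seeds and thresholds).
#' @export
run_pipeline <- function(matrix, lineages = NULL,
                         mining_config = virorules::mining_config(),
                         calib_config = virorules::calibration_config(),
                         min_support = 0, min_lift = 0,
                         out_dir = NULL) {
  if (is.character(matrix)) {
    if (!file.exists(matrix)) .stopf("config error: matrix file not found: %s", matrix)
    matrix <- read_presence_matrix(matrix, "wide")
  }
  matrix <- validate_pa_matrix(matrix)
  if (is.character(lineages)) {
    if (!file.exists(lineages)) .stopf("config error: lineage file not found: %s", lineages)
    lineages <- read_lineages(lineages, vocabulary = colnames(matrix))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  summary <- stage("summarize", cohort_summary(matrix))
  candidates <- stage("mine", enumerate_candidate_rules(matrix, mining_config))
  null_pool <- stage(
    "null",
    build_null_lift_distribution(matrix, mining_config, calib_config)
  )
  calibration <- stage("calibrate", calibrate_dynamic_thresholds(null_pool, calib_config))
  significant <- stage(
    "filter",
    filter_significant_rules(candidates, calibration,
      min_support = min_support, min_lift = min_lift
    )
  )
  significant <- stage("classify", classify_rules(significant))
  grouped <- stage("group", group_rules(significant))
  census <- stage("census", type_census(significant))
  validation <- if (!is.null(lineages)) {
    stage("validate", summarize_validation(significant, lineages))
  } else {
    NULL
  }

  counts <- list(
    n_strains = summary$n_strains,
    n_viruses = summary$n_viruses,
    n_strains_mined = attr(candidates, "n_strains_mined"),
    thresholds = attr(candidates, "thresholds"),
    seed = calib_config$seed,
    alpha = calib_config$alpha,
    n_permutations = calib_config$n_permutations,
    n_candidates = nrow(candidates),
    n_significant = nrow(significant),
    n_null_rules = nrow(null_pool),
    global_lift_threshold = calibration$global_threshold,
    census = as.list(census)
  )
  bundle <- list(
    summary = summary, candidates = candidates, calibration = calibration,
    significant = significant, grouped = grouped, census = census,
    validation = validation, counts = counts
  )
  class(bundle) <- "pipeline_bundle"
  if (!is.null(out_dir)) export_report(bundle, out_dir)
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf(
    "pipeline: %d strains x %d viruses -> %d candidates -> %d significant rules\n",
    x$counts$n_strains, x$counts$n_viruses, x$counts$n_candidates, x$counts$n_significant
  ))
  invisible(x)
}

#' Export a pipeline bundle to disk
#'
#' Writes `candidates.csv`, `significant.csv`, `grouped_rules.csv`,
#' `calibration.json`, `summary.json` (machine-readable stage counts,
#' thresholds, seed, census and validation accuracies), `report.txt`
#' (human-readable), and `validation.csv` when validation ran. The JSON
#' carries no timestamps, so a rerun with the same seed is byte-identical.
#'
#' @param bundle a `pipeline_bundle`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
export_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_rules_table(bundle$candidates, file.path(out_dir, "candidates.csv"))
  write_rules_table(bundle$significant, file.path(out_dir, "significant.csv"))
  utils::write.csv(bundle$grouped, file.path(out_dir, "grouped_rules.csv"), row.names = FALSE)
  write_calibration_table(bundle$calibration, file.path(out_dir, "calibration.json"))
  if (!is.null(bundle$validation)) {
    write_validation_report(bundle$validation, file.path(out_dir, "validation.csv"))
  }
  summary_json <- bundle$counts
  summary_json$histogram <- as.list(bundle$summary$histogram)
  if (!is.null(bundle$validation)) {
    summary_json$validation_overall <- bundle$validation$overall
  }
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  lines <- c(
    "virus co-occurrence rule pipeline",
    sprintf("strains: %d (mined: %d)  viruses: %d",
      bundle$counts$n_strains, bundle$counts$n_strains_mined, bundle$counts$n_viruses
    ),
    sprintf(
      "min support: %.5f  min confidence: %.5f",
      bundle$counts$thresholds$min_support, bundle$counts$thresholds$min_confidence
    ),
    sprintf(
      "seed: %d  alpha: %g  permutations: %d",
      bundle$counts$seed, bundle$counts$alpha, bundle$counts$n_permutations
    ),
    sprintf(
      "candidates: %d  significant: %d  (global lift threshold %.4f)",
      bundle$counts$n_candidates, bundle$counts$n_significant,
      bundle$counts$global_lift_threshold
    ),
    "rule type census:",
    sprintf("  %s: %d", names(bundle$census), bundle$census)
  )
  if (!is.null(bundle$validation) && nrow(bundle$validation$overall) > 0L) {
    lines <- c(lines, "validation accuracy (overall):", sprintf(
      "  %s: %d/%d = %.1f%%",
      bundle$validation$overall$rule_form,
      bundle$validation$overall$confirmed,
      bundle$validation$overall$predicted,
      bundle$validation$overall$accuracy
    ))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
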