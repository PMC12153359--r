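#' Calibration configuration for dynamic Lift thresholds
#'
#' The significance filter retains a rule only if its Lift exceeds the
#' (1 - alpha) empirical quantile of null Lifts from permuted matrices, with
#' a separate threshold for each (Support, Confidence) stratum: weakly
#' supported rules have noisier Lift estimates and need a higher cutoff, so
#' a single global Lift floor would either leak false positives at low
#' support or discard real signal at high support.
#'
#' @param alpha target false-positive rate among candidate rules under the
#'   independence null (default 0.05).
#' @param n_permutations number of column-permuted matrices pooled into the
#'   null (default 200).
#' @param seed master seed; per-permutation seeds are derived from it
#'   deterministically.
#' @param support_bins,confidence_bins numeric bin edges covering \[0, 1\];
#'   `NULL` (default) uses deciles of the pooled null rule metrics.
#' @return a list of class `calibration_config`.
#' @export
calibration_config <- function(alpha = 0.05, n_permutations = 200L, seed = 1L,
                               support_bins = NULL, confidence_bins = NULL) {
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  n_permutations <- as.integer(n_permutations)
  for (b in list(support_bins, confidence_bins)) {
    if (!is.null(b) && (min(b) > 0 || max(b) < 1)) .stopf("bins must cover [0, 1]")
  }
  structure(
    list(
      alpha = alpha, n_permutations = n_permutations, seed = as.integer(seed),
      support_bins = support_bins, confidence_bins = confidence_bins
    ),
    class = "calibration_config"
  )
}

#' Independently permute each virus column
#'
#' Realizes the independence null: each column is shuffled across strains on
#' its own, which preserves every per-virus prevalence (column sums are
#' unchanged) and the strain count exactly, while destroying cross-virus
#' association in expectation.
#'
#' @param x a [pa_matrix()].
#' @param seed integer seed; the same seed reproduces the same permutation.
#' @return a permuted [pa_matrix()].
#' @export
permute_matrix_columns <- function(x, seed = NULL) {
  X <- unclass(validate_pa_matrix(x))
  .with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      X[, j] <- X[sample.int(nrow(X)), j]
    }
  })
  pa_matrix(X)
}

# Bernoulli alternative to column permutation (plug-in prevalences); kept
# behind a flag for sensitivity analysis. Does not preserve column sums
# exactly.
.bernoulli_null <- function(x, seed = NULL) {
  X <- unclass(x)
  p <- colMeans(X)
  .with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      X[, j] <- as.integer(stats::runif(nrow(X)) < p[j])
    }
  })
  pa_matrix(X)
}

#' Pool null rule metrics from permuted matrices
#'
#' Mines each of `n_permutations` column-permuted copies of `x` with the
#' same mining configuration as the observed data and pools the (Support,
#' Confidence, Lift) triples of every null candidate rule.
#'
#' @param x a [pa_matrix()].
#' @param mining_config a [mining_config()].
#' @param calib_config a [calibration_config()].
#' @param null_model `"permutation"` (default; preserves prevalences exactly)
#'   or `"bernoulli"` (independent draws at plug-in prevalences).
#' @return a data frame of class `null_pool` with columns `support`,
#'   `confidence`, `lift` and attribute `n_permutations`.
#' @export
build_null_lift_distribution <- function(x, mining_config = mining_config(),
                                         calib_config = calibration_config(),
                                         null_model = c("permutation", "bernoulli")) {
  null_model <- match.arg(null_model)
  if (calib_config$n_permutations < 1L) .stopf("empty null: n_permutations must be >= 1")
  seeds <- .derive_seeds(calib_config$seed, calib_config$n_permutations)
  fast <- mining_config$max_lhs_size == 1L
  thr <- NULL
  sup <- conf <- lift <- vector("list", calib_config$n_permutations)
  for (i in seq_len(calib_config$n_permutations)) {
    perm <- if (null_model == "permutation") {
      permute_matrix_columns(x, seeds[i])
    } else {
      .bernoulli_null(x, seeds[i])
    }
    if (fast) {
      X <- .mined_rows(perm, mining_config$mined_strains)
      thr <- .resolve_thresholds(mining_config, ncol(X))
      m <- .mine_pairs(X, thr$min_support, thr$min_confidence, metrics_only = TRUE)
    } else {
      m <- enumerate_candidate_rules(perm, mining_config)
    }
    sup[[i]] <- m$support
    conf[[i]] <- m$confidence
    lift[[i]] <- m$lift
  }
  out <- data.frame(
    support = unlist(sup), confidence = unlist(conf), lift = unlist(lift)
  )
  attr(out, "n_permutations") <- calib_config$n_permutations
  class(out) <- c("null_pool", "data.frame")
  out
}

# Decile edges of a metric, forced to span [0, 1].
.decile_edges <- function(v) {
  q <- unname(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1), type = 7, names = FALSE))
  sort(unique(c(0, q, 1)))
}

.assign_stratum <- function(values, edges) {
  if (edges[1L] > 0 || edges[length(edges)] < 1) {
    .stopf("bins must cover [0, 1]")
  }
  # left-closed bins; the final bin is closed on both sides so 1.0 belongs
  findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Calibrate stratified Lift thresholds from a null pool
#'
#' Within each (Support bin x Confidence bin) stratum, the Lift threshold is
#' the empirical (1 - alpha) quantile (R's default type-7 definition) of the
#' null Lifts falling in that stratum. Strata that received no null rules are
#' flagged and fall back to the global (1 - alpha) quantile of the whole
#' pool.
#'
#' @param null_pool output of [build_null_lift_distribution()].
#' @param calib_config a [calibration_config()].
#' @return a list of class `calibration_table`: `strata` (data frame with
#'   bin indices, edges, `lift_threshold`, `n_null_rules`, `fallback`),
#'   `support_bins`, `confidence_bins`, `global_threshold`, `alpha`.
#' @export
calibrate_dynamic_thresholds <- function(null_pool, calib_config = calibration_config()) {
  if (nrow(null_pool) == 0L) .stopf("empty null pool")
  sb <- calib_config$support_bins %||% .decile_edges(null_pool$support)
  cb <- calib_config$confidence_bins %||% .decile_edges(null_pool$confidence)
  q <- function(v) unname(stats::quantile(v, probs = 1 - calib_config$alpha, type = 7, names = FALSE))
  global_thr <- q(null_pool$lift)
  si <- .assign_stratum(null_pool$support, sb)
  ci <- .assign_stratum(null_pool$confidence, cb)
  ns <- length(sb) - 1L
  nc <- length(cb) - 1L
  grid <- expand.grid(support_bin = seq_len(ns), confidence_bin = seq_len(nc))
  cell <- (ci - 1L) * ns + si
  thr <- rep(global_thr, nrow(grid))
  n_null <- integer(nrow(grid))
  tab <- split(null_pool$lift, cell)
  idx <- as.integer(names(tab))
  thr[idx] <- vapply(tab, q, 0)
  n_null[idx] <- lengths(tab)
  out <- list(
    strata = data.frame(
      support_bin = grid$support_bin, confidence_bin = grid$confidence_bin,
      support_lo = sb[grid$support_bin], support_hi = sb[grid$support_bin + 1L],
      confidence_lo = cb[grid$confidence_bin], confidence_hi = cb[grid$confidence_bin + 1L],
      lift_threshold = thr, n_null_rules = n_null, fallback = n_null == 0L
    ),
    support_bins = sb, confidence_bins = cb,
    global_threshold = global_thr, alpha = calib_config$alpha
  )
  class(out) <- "calibration_table"
  out
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf(
    "calibration table: %d x %d (support x confidence) strata, alpha = %g\n",
    length(x$support_bins) - 1L, length(x$confidence_bins) - 1L, x$alpha
  ))
  cat(sprintf(
    "global lift threshold %.4f; %d strata on fallback\n",
    x$global_threshold, sum(x$strata$fallback)
  ))
  invisible(x)
}

#' Retain rules beating their stratum's Lift threshold
#'
#' A candidate is significant when its Lift strictly exceeds the threshold
#' of the (Support, Confidence) stratum it falls in. Optional global floors
#' (`min_support`, `min_lift`) reproduce published summary cutoffs.
#'
#' @param candidates a `rule_set` from [enumerate_candidate_rules()].
#' @param table a [calibrate_dynamic_thresholds()] result.
#' @param min_support,min_lift optional additional floors (default 0 = none).
#' @return the retained subset of `candidates`, with columns `significant`
#'   (all `TRUE`) and `lift_threshold_applied`, and attribute
#'   `n_candidates`.
#' @export
filter_significant_rules <- function(candidates, table, min_support = 0, min_lift = 0) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$significant <- logical(0)
    out$lift_threshold_applied <- numeric(0)
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  si <- .assign_stratum(candidates$support, table$support_bins)
  ci <- .assign_stratum(candidates$confidence, table$confidence_bins)
  ns <- length(table$support_bins) - 1L
  thr <- table$strata$lift_threshold[(ci - 1L) * ns + si]
  keep <- candidates$lift > thr &
    candidates$support >= min_support &
    candidates$lift >= min_lift
  out <- candidates[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  out$lift_threshold_applied <- thr[keep]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- nrow(candidates)
  attr(out, "n_strains_mined") <- attr(candidates, "n_strains_mined")
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Serialize and restore a calibration table as JSON
#'
#' @param table a `calibration_table`.
#' @param path JSON file path.
#' @export
write_calibration_table <- function(table, path) {
  payload <- list(
    alpha = table$alpha,
    support_bins = table$support_bins,
    confidence_bins = table$confidence_bins,
    global_threshold = table$global_threshold,
    strata = table$strata
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(
    strata = as.data.frame(p$strata),
    support_bins = as.numeric(p$support_bins),
    confidence_bins = as.numeric(p$confidence_bins),
    global_threshold = as.numeric(p$global_threshold),
    alpha = as.numeric(p$alpha)
  )
  class(out) <- "calibration_table"
  out
}

#' Empirical false-positive rate under the independence null
#'
#' Generates `n_replicates` matrices of mutually independent viruses from
#' `syn_config`, runs the full calibrate-then-filter procedure on each, and
#' returns the per-replicate proportion of candidate rules declared
#' significant. Since every mined rule on such data is a false positive,
#' the mean proportion estimates the procedure's FPR, which the dynamic
#' threshold is designed to hold at or below `calib_config$alpha`.
#'
#' @param n_replicates number of independent null datasets (default 100).
#' @param syn_config a [synthetic_config()] (planted structure ignored).
#' @param mining_cfg a [mining_config()].
#' @param calib_config a [calibration_config()]; its seed is the master seed
#'   for the whole experiment.
#' @return numeric vector of length `n_replicates`: the proportion of
#'   candidate rules retained in each replicate (0 when a replicate yields
#'   no candidates).
#' @export
estimate_null_fpr <- function(n_replicates = 100L,
                              syn_config = synthetic_config(),
                              mining_cfg = mining_config(),
                              calib_config = calibration_config()) {
  seeds <- .derive_seeds(calib_config$seed, 2L * n_replicates)
  vapply(seq_len(n_replicates), function(r) {
    m <- generate_null_matrix(syn_config, seed = seeds[2L * r - 1L])
    candidates <- enumerate_candidate_rules(m, mining_cfg)
    if (nrow(candidates) == 0L) {
      return(0)
    }
    cc <- calib_config
    cc$seed <- seeds[2L * r]
    pool <- build_null_lift_distribution(m, mining_cfg, cc)
    table <- calibrate_dynamic_thresholds(pool, cc)
    retained <- filter_significant_rules(candidates, table)
    nrow(retained) / nrow(candidates)
  }, 0)
}
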