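#' Presence/absence matrices of viruses across fungal strains
#'
#' A `pa_matrix` is an integer matrix with strains as rows and viruses as
#' columns; cell \eqn{x_{sv} = 1} when virus \eqn{v} was detected (RT-PCR) in
#' strain \eqn{s} and 0 otherwise. It is the single source of truth for every
#' probability used downstream: per-virus prevalence is the column mean and
#' itemset supports are row-wise co-occurrence frequencies.
#'
#' @param x a numeric or integer matrix with values in \{0, 1\}, with unique,
#'   non-empty row names (strain ids) and column names (virus ids).
#' @return an object of class `pa_matrix`.
#' @examples
#' m <- pa_matrix(matrix(c(1, 0, 1, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("vA", "vB"))
#' ))
#' prevalence(m)
#' @export
pa_matrix <- function(x) {
  if (!is.matrix(x)) .stopf("`x` must be a matrix")
  storage.mode(x) <- "integer"
  class(x) <- c("pa_matrix", "matrix", "array")
  validate_pa_matrix(x)
}

#' @rdname pa_matrix
#' @export
validate_pa_matrix <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    .stopf("strain ids (row names) and virus ids (column names) are required")
  }
  if (nrow(x) == 0L || ncol(x) == 0L) .stopf("matrix must have at least one strain and one virus")
  if (anyDuplicated(rownames(x))) {
    .stopf("duplicate strain id: %s", rownames(x)[duplicated(rownames(x))][1L])
  }
  if (anyDuplicated(colnames(x))) {
    .stopf("duplicate virus id: %s", colnames(x)[duplicated(colnames(x))][1L])
  }
  bad <- which(is.na(x) | !(x == 0L | x == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    .stopf(
      "invalid value at strain '%s', virus '%s': cells must be 0 or 1",
      rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]
    )
  }
  x
}

#' @rdname pa_matrix
#' @export
prevalence <- function(x) colMeans(unclass(x))

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf(
    "presence/absence matrix: %d strains x %d viruses (%.1f%% cells positive)\n",
    nrow(x), ncol(x), 100 * mean(x)
  ))
  invisible(x)
}

#' Read a presence/absence matrix from CSV/TSV
#'
#' Wide format: first column `strain_id`, one column per virus, cells 0/1.
#' Long format: columns `strain_id`, `virus_id`, `present`; pairs not listed
#' default to absent (0), matching the presence-oriented RT-PCR tables the
#' format mirrors. Duplicate (strain, virus) entries in long format are an
#' error.
#'
#' @param path path to a CSV (or TSV, autodetected by extension) file.
#' @param format `"wide"` or `"long"`.
#' @return a [pa_matrix()].
#' @export
read_presence_matrix <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE, quote = "\""
  )
  if (format == "wide") {
    if (ncol(df) < 2L) .stopf("wide file needs a strain-id column plus at least one virus column")
    if (anyDuplicated(df[[1L]])) {
      .stopf("duplicate strain id: %s", df[[1L]][duplicated(df[[1L]])][1L])
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    pa_matrix(m)
  } else {
    need <- c("strain_id", "virus_id", "present")
    if (!all(need %in% names(df))) {
      .stopf("long file must have columns: %s", paste(need, collapse = ", "))
    }
    key <- paste(df$strain_id, df$virus_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE][1L, ]
      .stopf("duplicate entry for strain '%s', virus '%s'", d$strain_id, d$virus_id)
    }
    strains <- unique(as.character(df$strain_id))
    viruses <- sort(unique(as.character(df$virus_id)))
    m <- matrix(0L, length(strains), length(viruses), dimnames = list(strains, viruses))
    m[cbind(
      match(as.character(df$strain_id), strains),
      match(as.character(df$virus_id), viruses)
    )] <- as.integer(df$present)
    pa_matrix(m)
  }
}

#' Write a presence/absence matrix as wide CSV
#'
#' @param x a [pa_matrix()].
#' @param path output path.
#' @export
write_presence_matrix <- function(x, path) {
  df <- data.frame(strain_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a virome survey cohort
#'
#' Computes per-virus prevalence counts, per-strain virus counts, and the
#' co-infection histogram over the reporting bins
#' \{0, 1, 2, 3--5, 6--10, 11--15, 16--20, >=21\}.
#'
#' @param x a [pa_matrix()].
#' @return a list of class `cohort_summary` with elements `n_strains`,
#'   `n_viruses`, `virus_counts` (strains per virus), `strain_counts`
#'   (viruses per strain) and `histogram` (named bin counts, summing to the
#'   number of strains).
#' @export
cohort_summary <- function(x) {
  x <- validate_pa_matrix(x)
  per_strain <- rowSums(unclass(x))
  per_virus <- colSums(unclass(x))
  edges <- c(0, 1, 2, 3, 6, 11, 16, 21, Inf)
  labels <- c("0", "1", "2", "3-5", "6-10", "11-15", "16-20", ">=21")
  bin <- cut(per_strain, breaks = edges, labels = labels, right = FALSE)
  hist <- table(bin)
  out <- list(
    n_strains = nrow(x),
    n_viruses = ncol(x),
    virus_counts = per_virus,
    strain_counts = per_strain,
    histogram = stats::setNames(as.integer(hist), labels)
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort: %d strains, %d viruses\n", x$n_strains, x$n_viruses))
  cat("viruses per strain:\n")
  print(x$histogram)
  invisible(x)
}

#' Read parent/offspring lineage files
#'
#' A lineage file is a CSV with columns `parent_id`, `member_id`,
#' `role` (`parent` or `offspring`), and `viruses` (semicolon-separated virus
#' ids; empty for a virus-free member). One `lineage` object is built per
#' parent; offspring order follows the file.
#'
#' @param path path to the lineage CSV.
#' @param vocabulary optional character vector of known virus ids; any virus
#'   token outside it is an error.
#' @return a list of [lineage()] objects, named by parent id.
#' @export
read_lineages <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parent_id", "member_id", "role", "viruses")
  if (!all(need %in% names(df))) {
    .stopf("lineage file must have columns: %s", paste(need, collapse = ", "))
  }
  if (!all(df$role %in% c("parent", "offspring"))) {
    .stopf("role must be 'parent' or 'offspring'")
  }
  parse_viruses <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
  }
  out <- list()
  for (pid in unique(df$parent_id)) {
    sub <- df[df$parent_id == pid, , drop = FALSE]
    prow <- sub[sub$role == "parent", , drop = FALSE]
    if (nrow(prow) != 1L) .stopf("parent '%s' must have exactly one 'parent' row", pid)
    offs <- sub[sub$role == "offspring", , drop = FALSE]
    off_sets <- lapply(offs$viruses, parse_viruses)
    names(off_sets) <- offs$member_id
    out[[pid]] <- lineage(
      parent_id = pid,
      parent_viruses = parse_viruses(prow$viruses),
      offspring = off_sets,
      vocabulary = vocabulary
    )
  }
  out
}

#' Construct a parent/offspring lineage
#'
#' @param parent_id strain id of the parent.
#' @param parent_viruses character vector of virus ids detected in the parent.
#' @param offspring named list of character vectors: virus ids detected in
#'   each single-spore offspring, protoplast regenerant, or transfectant.
#' @param origin one of `"single_spore"`, `"protoplast_regenerant"`,
#'   `"transfectant"`.
#' @param vocabulary optional known virus ids for validation.
#' @return an object of class `lineage`. Lineages with zero offspring are
#'   valid containers but flagged `usable = FALSE` for validation.
#' @export
lineage <- function(parent_id, parent_viruses, offspring = list(),
                    origin = c("single_spore", "protoplast_regenerant", "transfectant"),
                    vocabulary = NULL) {
  origin <- match.arg(origin)
  parent_viruses <- unique(as.character(parent_viruses))
  offspring <- lapply(offspring, function(v) unique(as.character(v)))
  if (!is.null(vocabulary)) {
    all_v <- unique(c(parent_viruses, unlist(offspring, use.names = FALSE)))
    unknown <- setdiff(all_v, vocabulary)
    if (length(unknown) > 0L) {
      .stopf("unknown virus id(s): %s", paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(
      parent_id = as.character(parent_id),
      parent_viruses = parent_viruses,
      offspring = offspring,
      origin = origin,
      usable = length(offspring) >= 1L
    ),
    class = "lineage"
  )
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf(
    "lineage %s (%s): %d parental viruses, %d offspring%s\n",
    x$parent_id, x$origin, length(x$parent_viruses), length(x$offspring),
    if (x$usable) "" else " [unusable for validation]"
  ))
  invisible(x)
}

.rules_columns <- c(
  "lhs_items", "rhs_item", "support", "confidence", "lift",
  "rule_form", "rule_type", "significant", "lift_threshold_applied"
)

#' Write and read rule tables
#'
#' Rules are exported as UTF-8 CSV with columns `lhs_items` (items joined by
#' `;`), `rhs_item`, `support`, `confidence`, `lift`, `rule_form`,
#' `rule_type`, `significant`, and `lift_threshold_applied`. Columns the rule
#' set does not carry yet (e.g. `rule_type` before classification) are
#' written as NA and restored as such, so `read_rules_table(write_rules_table(x))`
#' is the identity on the populated columns.
#'
#' @param rules a rule data frame as produced by
#'   [enumerate_candidate_rules()], [filter_significant_rules()] or
#'   [classify_rules()].
#' @param path output CSV path.
#' @export
write_rules_table <- function(rules, path) {
  out <- as.data.frame(rules)
  for (col in .rules_columns) {
    if (is.null(out[[col]])) out[[col]] <- rep(NA, nrow(out))
  }
  out <- out[, .rules_columns, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_rules_table
#' @export
read_rules_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("support", "confidence", "lift", "lift_threshold_applied")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$significant <- as.logical(df$significant)
  df
}
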