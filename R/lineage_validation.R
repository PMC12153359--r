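#' Screen rules applicable to a parent strain
#'
#' A mined rule is "predicted" for a strain when every virus it mentions
#' (antecedent and consequent alike) is among the viruses detected in that
#' strain, so the offspring of the strain can in principle falsify it. An
#' alternative reading — requiring only that the antecedent be satisfiable —
#' is available via `semantics = "lhs_satisfiable"`, which keeps any rule
#' whose antecedent presence-items are all carried by the parent.
#'
#' @param rules a `rule_set` (normally the significant set).
#' @param lineage a [lineage()].
#' @param semantics `"subset"` (default) or `"lhs_satisfiable"`.
#' @return the applicable subset of `rules`.
#' @export
select_applicable_rules <- function(rules, lineage, semantics = c("subset", "lhs_satisfiable")) {
  semantics <- match.arg(semantics)
  if (nrow(rules) == 0L) {
    return(rules)
  }
  lhs_list <- .split_items(rules$lhs_items)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    lhs <- lhs_list[[i]]
    if (semantics == "subset") {
      all(c(.item_virus(lhs), .item_virus(rules$rhs_item[i])) %in% lineage$parent_viruses)
    } else {
      pres <- .item_virus(lhs)[.item_state(lhs)]
      all(pres %in% lineage$parent_viruses)
    }
  }, logical(1L))
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.items_hold <- function(items, virus_set) {
  all((.item_virus(items) %in% virus_set) == .item_state(items))
}

#' Test one rule against every offspring of a lineage
#'
#' On each offspring's virus set the rule is read as a material implication:
#' it HOLDS when the antecedent is not satisfied (vacuously) or when both
#' antecedent and consequent are satisfied. The rule is "confirmed" only if
#' it holds in every offspring — a single counterexample offspring falsifies
#' it.
#'
#' @param rule one row of a `rule_set` (a list or single-row data frame with
#'   `lhs_items` and `rhs_item`).
#' @param lineage a [lineage()] with at least one offspring.
#' @return a list with `holds_count` and `confirmed`.
#' @export
evaluate_rule_on_lineage <- function(rule, lineage) {
  if (length(lineage$offspring) == 0L) .stopf("lineage '%s' has no offspring", lineage$parent_id)
  lhs <- .split_items(rule$lhs_items)[[1L]]
  rhs <- rule$rhs_item
  holds <- vapply(lineage$offspring, function(vs) {
    !.items_hold(lhs, vs) || .items_hold(rhs, vs)
  }, logical(1L))
  list(holds_count = sum(holds), confirmed = all(holds))
}

#' Validate mined rules against offspring virus compositions
#'
#' For each lineage, screens the applicable ("predicted") rules with
#' [select_applicable_rules()], evaluates each against all offspring, and
#' reports predicted/confirmed counts and the accuracy percentage
#' (100 x confirmed / predicted), split by rule form, plus a pooled overall
#' row per rule form. Lineages without offspring are skipped. A lineage/form
#' with zero predicted rules reports accuracy `NA` (undefined), never 0.
#'
#' @param rules a `rule_set` (normally the significant set).
#' @param lineages a list of [lineage()] objects (e.g. [read_lineages()]).
#' @param semantics passed to [select_applicable_rules()].
#' @return a list of class `validation_report`: `per_lineage` (data frame
#'   with columns `strain`, `n_viruses`, `n_offspring`, `rule_form`,
#'   `predicted`, `confirmed`, `accuracy`), `overall` (per rule form),
#'   `rule_results` (per-rule detail).
#' @export
summarize_validation <- function(rules, lineages, semantics = "subset") {
  if (inherits(lineages, "lineage")) lineages <- list(lineages)
  per <- list()
  detail <- list()
  for (ln in lineages) {
    if (!ln$usable) next
    appl <- select_applicable_rules(rules, ln, semantics = semantics)
    if (nrow(appl) > 0L) {
      res <- lapply(seq_len(nrow(appl)), function(i) {
        evaluate_rule_on_lineage(appl[i, , drop = FALSE], ln)
      })
      appl$holds_count <- vapply(res, `[[`, 0, "holds_count")
      appl$confirmed <- vapply(res, `[[`, NA, "confirmed")
      appl$strain <- ln$parent_id
      detail[[length(detail) + 1L]] <- appl
    }
    for (form in unique(rules$rule_form)) {
      sub <- appl[appl$rule_form == form, , drop = FALSE]
      per[[length(per) + 1L]] <- data.frame(
        strain = ln$parent_id,
        n_viruses = length(ln$parent_viruses),
        n_offspring = length(ln$offspring),
        rule_form = form,
        predicted = nrow(sub),
        confirmed = if (nrow(sub) > 0L) sum(sub$confirmed) else 0L,
        accuracy = if (nrow(sub) > 0L) 100 * sum(sub$confirmed) / nrow(sub) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  per_lineage <- if (length(per) > 0L) {
    do.call(rbind, per)
  } else {
    data.frame(
      strain = character(0), n_viruses = integer(0), n_offspring = integer(0),
      rule_form = character(0), predicted = integer(0), confirmed = integer(0),
      accuracy = numeric(0), stringsAsFactors = FALSE
    )
  }
  overall <- do.call(rbind, lapply(split(per_lineage, per_lineage$rule_form), function(d) {
    data.frame(
      rule_form = d$rule_form[1L],
      predicted = sum(d$predicted),
      confirmed = sum(d$confirmed),
      accuracy = if (sum(d$predicted) > 0L) 100 * sum(d$confirmed) / sum(d$predicted) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(overall) <- NULL
  out <- list(
    per_lineage = per_lineage,
    overall = overall %||% data.frame(
      rule_form = character(0), predicted = integer(0),
      confirmed = integer(0), accuracy = numeric(0)
    ),
    rule_results = if (length(detail) > 0L) do.call(rbind, detail) else NULL
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("rule validation against offspring virus compositions\n")
  print(x$per_lineage)
  cat("overall:\n")
  print(x$overall)
  invisible(x)
}

#' Write a validation report as CSV
#'
#' Mirrors the per-strain bookkeeping of the validation experiment: strain,
#' number of parental viruses, number of offspring, predicted, confirmed and
#' accuracy per rule form, with pooled `overall` rows appended.
#'
#' @param report a `validation_report`.
#' @param path output CSV path.
#' @export
write_validation_report <- function(report, path) {
  per <- report$per_lineage
  ov <- report$overall
  if (nrow(ov) > 0L) {
    ov <- data.frame(
      strain = "overall", n_viruses = NA_integer_, n_offspring = NA_integer_,
      ov,
      stringsAsFactors = FALSE
    )
    per <- rbind(per, ov)
  }
  utils::write.csv(per, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
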