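#' Classify rules by their presence/absence pattern
#'
#' One-to-one rules fall into four types: Type I, absence explains absence
#' (\{A=F\} => \{B=F\}); Type II, presence explains presence; Type III,
#' presence explains absence; Type IV, absence explains presence. Rules with
#' two or three antecedent viruses are labelled by their state tuple, e.g.
#' `"TT=>F"` or `"TFF=>T"`, with antecedent states sorted (T before F) since
#' the antecedent itemset is unordered. Classification depends only on item
#' states, never on metrics.
#'
#' @param rules a `rule_set` data frame.
#' @return `rules` with a `rule_type` character column added.
#' @examples
#' # {A=F} => {B=F} is Type I; {A=T,B=T} => {C=F} is "TT=>F"
#' @export
classify_rules <- function(rules) {
  if (nrow(rules) == 0L) {
    rules$rule_type <- character(0)
    return(rules)
  }
  lhs_states <- lapply(.split_items(rules$lhs_items), .item_state)
  if (any(lengths(lhs_states) > 3L)) .stopf("unsupported: antecedents larger than 3 items")
  rhs_state <- .item_state(rules$rhs_item)
  rules$rule_type <- vapply(seq_len(nrow(rules)), function(i) {
    ls <- lhs_states[[i]]
    if (length(ls) == 1L) {
      if (!ls && !rhs_state[i]) {
        "I"
      } else if (ls && rhs_state[i]) {
        "II"
      } else if (ls && !rhs_state[i]) "III" else "IV"
    } else {
      lhs_code <- paste(ifelse(sort(ls, decreasing = TRUE), "T", "F"), collapse = "")
      paste0(lhs_code, "=>", if (rhs_state[i]) "T" else "F")
    }
  }, "")
  rules
}

#' Tabulate rule types
#'
#' @param rules a `rule_set`, classified or not (classification is applied
#'   if the `rule_type` column is missing).
#' @return a named integer vector of counts; the counts partition the rule
#'   set, so they sum to `nrow(rules)`.
#' @export
type_census <- function(rules) {
  if (is.null(rules$rule_type)) rules <- classify_rules(rules)
  if (nrow(rules) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(rules$rule_type)
  stats::setNames(as.integer(tab), names(tab))
}

#' Grouped antecedent-by-consequent rule matrix
#'
#' The tabular twin of a balloon-plot view: rules are grouped by their
#' (antecedent itemset, consequent item) key and each cell aggregates the
#' member count, maximum Lift and maximum Support. Every rule contributes to
#' exactly one cell.
#'
#' @param rules a `rule_set` with metrics.
#' @return a data frame with columns `lhs_group`, `rhs_group`, `count`,
#'   `max_lift`, `max_support`, ordered canonically.
#' @export
group_rules <- function(rules) {
  if (nrow(rules) == 0L) {
    return(data.frame(
      lhs_group = character(0), rhs_group = character(0),
      count = integer(0), max_lift = numeric(0), max_support = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  key <- paste(rules$lhs_items, rules$rhs_item, sep = " => ")
  agg <- lapply(split(seq_len(nrow(rules)), key), function(idx) {
    data.frame(
      lhs_group = rules$lhs_items[idx[1L]],
      rhs_group = rules$rhs_item[idx[1L]],
      count = length(idx),
      max_lift = max(rules$lift[idx]),
      max_support = max(rules$support[idx]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$lhs_group, out$rhs_group, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
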