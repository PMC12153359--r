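# Independent brute-force rule enumerator used as the oracle for the Apriori
# miner. It shares no code with the package: supports are counted by direct
# logical conjunction over strains, and every (antecedent viruses, states,
# consequent) combination is enumerated exhaustively with no pruning.

bf_item_columns <- function(X) {
  vn <- colnames(X)
  cols <- list()
  for (v in vn) {
    cols[[paste0(v, "=T")]] <- X[, v] == 1L
    cols[[paste0(v, "=F")]] <- X[, v] == 0L
  }
  cols
}

bf_enumerate <- function(x, max_lhs, min_support, min_confidence) {
  X <- unclass(x)
  n <- nrow(X)
  vn <- sort(colnames(X), method = "radix")
  cols <- bf_item_columns(X)
  forms <- c("one_to_one", "two_to_one", "three_to_one")
  out <- list()
  for (k in seq_len(max_lhs)) {
    lhs_virus_sets <- utils::combn(vn, k, simplify = FALSE)
    state_grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))
    for (lv in lhs_virus_sets) {
      for (si in seq_len(nrow(state_grid))) {
        states <- unlist(state_grid[si, ], use.names = FALSE)
        lhs_items <- paste0(lv, "=", ifelse(states, "T", "F"))
        lhs_ind <- Reduce(`&`, cols[lhs_items])
        s_lhs <- sum(lhs_ind) / n
        for (rv in setdiff(vn, lv)) {
          for (rs in c(TRUE, FALSE)) {
            rhs_item <- paste0(rv, "=", ifelse(rs, "T", "F"))
            s_rhs <- sum(cols[[rhs_item]]) / n
            if (s_lhs == 0 || s_rhs == 0) next
            s_all <- sum(lhs_ind & cols[[rhs_item]]) / n
            conf <- s_all / s_lhs
            if (s_all < min_support || conf < min_confidence) next
            out[[length(out) + 1L]] <- data.frame(
              lhs_items = paste(lhs_items, collapse = ";"),
              rhs_item = rhs_item,
              rule_form = forms[k],
              support = s_all, confidence = conf,
              lift = s_all / (s_lhs * s_rhs),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(
      lhs_items = character(0), rhs_item = character(0), rule_form = character(0),
      support = numeric(0), confidence = numeric(0), lift = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$rule_form, forms), res$lhs_items, res$rhs_item,
    method = "radix"
  ), , drop = FALSE]
  rownames(res) <- NULL
  res
}

bf_support <- function(x, items) {
  cols <- bf_item_columns(unclass(x))
  viruses <- sub("=[TF]$", "", items)
  if (anyDuplicated(viruses)) {
    states <- substring(items, nchar(items))
    if (any(tapply(states, viruses, function(s) length(unique(s))) > 1)) {
      return(0)
    }
  }
  mean(Reduce(`&`, cols[unique(items)]))
}
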