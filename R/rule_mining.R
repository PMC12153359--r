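#' Mining configuration
#'
#' Thresholds default to the survey's convention: minimum Support and
#' Confidence of 3/V, where V is the number of virus species in the matrix
#' (almost every strain carries three or more viruses, so a real co-occurrence
#' pattern involves at least three strains' worth of signal). Probabilities
#' are estimated over the mined strain subset; by default strains carrying no
#' virus at all are excluded, so a 406-strain survey with one virus-free
#' strain is mined over 405.
#'
#' @param max_lhs_size antecedent size: 1 (one-to-one), 2 (two-to-one) or
#'   3 (three-to-one). Rules with every antecedent size up to this value are
#'   returned.
#' @param min_support,min_confidence thresholds in \[0, 1\]; `NULL` means
#'   3/V, resolved against the matrix at mining time.
#' @param mined_strains `"infected"` (drop all-zero strains), `"all"`, or a
#'   character/logical vector selecting strains.
#' @return a list of class `mining_config`.
#' @export
mining_config <- function(max_lhs_size = 1L, min_support = NULL,
                          min_confidence = NULL, mined_strains = "infected") {
  max_lhs_size <- as.integer(max_lhs_size)
  if (!max_lhs_size %in% 1:3) .stopf("max_lhs_size must be 1, 2 or 3")
  for (thr in list(min_support, min_confidence)) {
    if (!is.null(thr) && (thr < 0 || thr > 1)) .stopf("thresholds must lie in [0, 1]")
  }
  structure(
    list(
      max_lhs_size = max_lhs_size, min_support = min_support,
      min_confidence = min_confidence, mined_strains = mined_strains
    ),
    class = "mining_config"
  )
}

.resolve_thresholds <- function(config, n_viruses) {
  default <- 3 / n_viruses
  list(
    min_support = if (is.null(config$min_support)) default else config$min_support,
    min_confidence = if (is.null(config$min_confidence)) default else config$min_confidence
  )
}

.mined_rows <- function(x, mined_strains) {
  if (is.character(mined_strains) && length(mined_strains) == 1L &&
    mined_strains %in% c("infected", "all")) {
    if (mined_strains == "all") {
      return(unclass(x))
    }
    return(unclass(x)[rowSums(unclass(x)) > 0L, , drop = FALSE])
  }
  if (is.logical(mined_strains)) {
    return(unclass(x)[mined_strains, , drop = FALSE])
  }
  unclass(x)[match(mined_strains, rownames(x)), , drop = FALSE]
}

#' Support of an itemset
#'
#' The fraction of strains satisfying every item of the set: `"v=T"` items
#' require cell 1, `"v=F"` items require cell 0. A contradictory set (the
#' same virus required both present and absent) has support 0 by definition.
#'
#' @param x a [pa_matrix()] (or plain 0/1 matrix with virus column names).
#' @param itemset character vector of items, e.g. `c("vA=T", "vB=F")`.
#' @return a probability in \[0, 1\].
#' @examples
#' m <- pa_matrix(matrix(c(1, 1, 0, 1, 0, 0), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("vA", "vB"))
#' ))
#' itemset_support(m, c("vA=T", "vB=T"))
#' @export
itemset_support <- function(x, itemset) {
  if (length(itemset) == 0L) .stopf("empty itemset")
  viruses <- .item_virus(itemset)
  states <- .item_state(itemset)
  unknown <- setdiff(viruses, colnames(x))
  if (length(unknown) > 0L) .stopf("unknown virus id(s): %s", paste(unknown, collapse = ", "))
  # contradictory pairs {v=T, v=F}: support is 0 by definition
  if (any(tapply(states, viruses, function(s) length(unique(s))) > 1L)) {
    return(0)
  }
  keep <- !duplicated(paste(viruses, states))
  viruses <- viruses[keep]
  states <- states[keep]
  cols <- unclass(x)[, viruses, drop = FALSE]
  target <- matrix(as.integer(states), nrow(cols), length(states), byrow = TRUE)
  mean(rowSums(cols == target) == length(viruses))
}

#' Support, Confidence and Lift of a single rule
#'
#' For a rule LHS => RHS over virus presence/absence items:
#' Support \eqn{= P(\mathrm{LHS} \cap \mathrm{RHS})}, Confidence
#' \eqn{= P(\mathrm{LHS} \cap \mathrm{RHS}) / P(\mathrm{LHS})}, Lift
#' \eqn{= P(\mathrm{LHS} \cap \mathrm{RHS}) / [P(\mathrm{LHS}) P(\mathrm{RHS})]}.
#' Lift is 1 when antecedent and consequent occur independently, above 1 for
#' positive association, below 1 for avoidance.
#'
#' @inheritParams itemset_support
#' @param lhs character vector of antecedent items.
#' @param rhs a single consequent item.
#' @return a list with `support`, `confidence`, `lift`.
#' @export
compute_rule_metrics <- function(x, lhs, rhs) {
  if (length(rhs) != 1L) .stopf("rhs must be a single item")
  if (.item_virus(rhs) %in% .item_virus(lhs)) {
    .stopf("rhs virus '%s' also appears in the lhs", .item_virus(rhs))
  }
  s_lhs <- itemset_support(x, lhs)
  s_rhs <- itemset_support(x, rhs)
  if (s_lhs == 0 || s_rhs == 0) {
    .stopf("undefined metric: lhs or rhs has zero support")
  }
  s <- itemset_support(x, c(lhs, rhs))
  list(support = s, confidence = s / s_lhs, lift = s / (s_lhs * s_rhs))
}

.rule_forms <- c("one_to_one", "two_to_one", "three_to_one")

# Vectorised one-to-one miner. Works on a plain 0/1 matrix; returns metric
# vectors (and item strings unless metrics_only). The 2x2 table of each
# ordered virus pair is reconstructed from crossprod() and the marginals, so
# a 405 x 76 matrix is mined in about a millisecond -- this is what makes
# permutation calibration with hundreds of replicates affordable.
.mine_pairs <- function(X, min_support, min_confidence, metrics_only = FALSE) {
  n <- nrow(X)
  V <- ncol(X)
  cs <- colSums(X)
  N11 <- crossprod(X)
  Ti <- matrix(cs, V, V) # count of lhs virus i (rows)
  Tj <- matrix(cs, V, V, byrow = TRUE) # count of rhs virus j (cols)
  joint <- list(
    TT = N11, TF = Ti - N11,
    FT = Tj - N11, FF = n - Ti - Tj + N11
  )
  off <- which(row(N11) != col(N11))
  i_idx <- row(N11)[off]
  j_idx <- col(N11)[off]
  sup <- conf <- lift <- numeric(0)
  lhs_i <- rhs_j <- integer(0)
  lhs_s <- rhs_s <- logical(0)
  for (combo in names(joint)) {
    a <- substr(combo, 1L, 1L) == "T"
    b <- substr(combo, 2L, 2L) == "T"
    m_a <- if (a) cs[i_idx] else n - cs[i_idx]
    m_b <- if (b) cs[j_idx] else n - cs[j_idx]
    jnt <- joint[[combo]][off]
    s <- jnt / n
    keep <- m_a > 0L & m_b > 0L & s >= min_support & jnt / m_a >= min_confidence
    if (!any(keep)) next
    sup <- c(sup, s[keep])
    conf <- c(conf, (jnt / m_a)[keep])
    lift <- c(lift, (jnt * n / (m_a * m_b))[keep])
    lhs_i <- c(lhs_i, i_idx[keep])
    rhs_j <- c(rhs_j, j_idx[keep])
    lhs_s <- c(lhs_s, rep(a, sum(keep)))
    rhs_s <- c(rhs_s, rep(b, sum(keep)))
  }
  if (metrics_only) {
    return(list(support = sup, confidence = conf, lift = lift))
  }
  vn <- colnames(X)
  list(
    lhs_items = .item(vn[lhs_i], lhs_s), rhs_item = .item(vn[rhs_j], rhs_s),
    support = sup, confidence = conf, lift = lift
  )
}

# Generic Apriori over the 2V present/absent items for antecedents of size
# >= 2. Item j in 1..2V: odd = virus (j+1)/2 present, even = absent.
# Frequent itemsets are grown level-wise with the anti-monotone prune;
# contradictory candidates (both states of one virus) are discarded
# structurally. Indicator columns of level k-1 itemsets are reused to count
# level k in chunked elementwise products.
.apriori_itemsets <- function(X, min_support, max_size) {
  n <- nrow(X)
  V <- ncol(X)
  Z <- matrix(0, n, 2L * V)
  Z[, seq(1L, 2L * V, by = 2L)] <- X
  Z[, seq(2L, 2L * V, by = 2L)] <- 1 - X
  item_virus <- rep(seq_len(V), each = 2L)
  supp_env <- new.env(parent = emptyenv(), size = 4096L)
  item_supp <- colMeans(Z)
  for (j in seq_len(2L * V)) assign(as.character(j), item_supp[j], envir = supp_env)

  frequent <- which(item_supp >= min_support)
  levels_out <- list(matrix(frequent, ncol = 1L))
  W_prev <- Z[, frequent, drop = FALSE]
  sets_prev <- levels_out[[1L]]

  for (k in 2:max_size) {
    if (nrow(sets_prev) < 2L) {
      levels_out[[k]] <- matrix(integer(0), 0L, k)
      break
    }
    # join step: combine itemsets sharing their first k-2 items
    prefix <- if (k == 2L) rep("", nrow(sets_prev)) else {
      apply(sets_prev[, seq_len(k - 2L), drop = FALSE], 1L, paste, collapse = ",")
    }
    groups <- split(seq_len(nrow(sets_prev)), prefix)
    cand <- list()
    cand_from <- list()
    for (g in groups) {
      if (length(g) < 2L) next
      pairs <- utils::combn(g, 2L)
      a <- pairs[1L, ]
      b <- pairs[2L, ]
      last_a <- sets_prev[a, k - 1L]
      last_b <- sets_prev[b, k - 1L]
      ok <- item_virus[last_a] != item_virus[last_b] # structural contradiction prune
      if (!any(ok)) next
      lo <- pmin(last_a[ok], last_b[ok])
      hi <- pmax(last_a[ok], last_b[ok])
      base <- if (k == 2L) {
        matrix(integer(0), sum(ok), 0L)
      } else {
        sets_prev[a[ok], seq_len(k - 2L), drop = FALSE]
      }
      cand[[length(cand) + 1L]] <- cbind(base, lo, hi, deparse.level = 0L)
      cand_from[[length(cand_from) + 1L]] <- ifelse(last_a[ok] < last_b[ok], a[ok], b[ok])
    }
    if (length(cand) == 0L) {
      levels_out[[k]] <- matrix(integer(0), 0L, k)
      break
    }
    cand <- do.call(rbind, cand)
    cand_from <- unlist(cand_from)
    # anti-monotone prune: every (k-1)-subset must be frequent
    if (k > 2L) {
      prev_keys <- new.env(parent = emptyenv(), size = nrow(sets_prev) * 2L)
      apply(sets_prev, 1L, function(s) assign(paste(s, collapse = ","), TRUE, envir = prev_keys))
      ok <- vapply(seq_len(nrow(cand)), function(r) {
        all(vapply(seq_len(k), function(drop) {
          exists(paste(cand[r, -drop], collapse = ","), envir = prev_keys)
        }, logical(1L)))
      }, logical(1L))
      cand <- cand[ok, , drop = FALSE]
      cand_from <- cand_from[ok]
    }
    if (nrow(cand) == 0L) {
      levels_out[[k]] <- matrix(integer(0), 0L, k)
      break
    }
    # support counting, chunked to bound memory
    keep <- logical(nrow(cand))
    W_rows <- vector("list", 0L)
    sets_rows <- vector("list", 0L)
    chunk <- 5000L
    starts <- seq(1L, nrow(cand), by = chunk)
    for (s0 in starts) {
      idx <- s0:min(s0 + chunk - 1L, nrow(cand))
      W_c <- W_prev[, cand_from[idx], drop = FALSE] * Z[, cand[idx, k], drop = FALSE]
      sup_c <- colSums(W_c) / n
      ok_c <- sup_c >= min_support
      keep[idx] <- ok_c
      if (any(ok_c)) {
        W_rows[[length(W_rows) + 1L]] <- W_c[, ok_c, drop = FALSE]
        sets_rows[[length(sets_rows) + 1L]] <- cand[idx[ok_c], , drop = FALSE]
        kept_sup <- sup_c[ok_c]
        kept_set <- cand[idx[ok_c], , drop = FALSE]
        for (r in seq_along(kept_sup)) {
          assign(paste(kept_set[r, ], collapse = ","), kept_sup[r], envir = supp_env)
        }
      }
    }
    if (!any(keep)) {
      levels_out[[k]] <- matrix(integer(0), 0L, k)
      break
    }
    sets_prev <- do.call(rbind, sets_rows)
    W_prev <- do.call(cbind, W_rows)
    # canonical row order so downstream output is deterministic
    ord <- do.call(order, c(lapply(seq_len(k), function(cc) sets_prev[, cc]), list(method = "radix")))
    sets_prev <- sets_prev[ord, , drop = FALSE]
    W_prev <- W_prev[, ord, drop = FALSE]
    levels_out[[k]] <- sets_prev
  }
  list(levels = levels_out, supp_env = supp_env, item_virus = item_virus)
}

.items_to_strings <- function(items, virus_names) {
  .item(virus_names[(items + 1L) %/% 2L], items %% 2L == 1L)
}

#' Enumerate candidate association rules
#'
#' Runs the Apriori algorithm over the 2V items (each virus contributing a
#' present and an absent item) of the mined strain subset, and emits every
#' rule with a single consequent item, antecedent size up to
#' `config$max_lhs_size`, Support >= `min_support` and Confidence >=
#' `min_confidence`. Frequent-itemset generation uses the anti-monotone
#' prune (no superset of an infrequent set is counted) and contradictory
#' sets (\{v=T, v=F\}) are discarded structurally. `{A}=>{B}` and `{B}=>{A}`
#' are distinct candidates. Output order is canonical: rule form, then
#' antecedent items (lexicographic by virus id), then consequent.
#'
#' @param x a [pa_matrix()].
#' @param config a [mining_config()].
#' @return a data frame of class `rule_set` with columns `lhs_items`,
#'   `rhs_item`, `rule_form`, `support`, `confidence`, `lift`, and
#'   attributes `n_strains_mined` and `thresholds`.
#' @export
enumerate_candidate_rules <- function(x, config = mining_config()) {
  X <- .mined_rows(x, config$mined_strains)
  if (nrow(X) == 0L) .stopf("no strains left to mine after applying the strain mask")
  thr <- .resolve_thresholds(config, ncol(X))
  vn <- colnames(X)

  if (config$max_lhs_size == 1L) {
    res <- .mine_pairs(X, thr$min_support, thr$min_confidence)
    out <- data.frame(
      lhs_items = res$lhs_items, rhs_item = res$rhs_item,
      rule_form = rep("one_to_one", length(res$support)),
      support = res$support, confidence = res$confidence, lift = res$lift,
      stringsAsFactors = FALSE
    )
  } else {
    ap <- .apriori_itemsets(X, thr$min_support, config$max_lhs_size + 1L)
    supp_of <- function(items) {
      get(paste(items, collapse = ","), envir = ap$supp_env)
    }
    rows <- list()
    for (k in 2:(config$max_lhs_size + 1L)) {
      if (k > length(ap$levels)) break
      sets <- ap$levels[[k]]
      if (nrow(sets) == 0L) next
      for (r in seq_len(nrow(sets))) {
        S <- sets[r, ]
        s_all <- supp_of(S)
        for (pos in seq_len(k)) {
          lhs <- S[-pos]
          rhs <- S[pos]
          s_lhs <- supp_of(lhs)
          s_rhs <- supp_of(rhs)
          if (s_lhs == 0 || s_rhs == 0) next
          conf <- s_all / s_lhs
          if (conf < thr$min_confidence) next
          rows[[length(rows) + 1L]] <- list(
            lhs = .join_items(.items_to_strings(lhs, vn)),
            rhs = .items_to_strings(rhs, vn),
            form = .rule_forms[k - 1L],
            support = s_all, confidence = conf, lift = conf / s_rhs
          )
        }
      }
    }
    out <- if (length(rows) == 0L) {
      data.frame(
        lhs_items = character(0), rhs_item = character(0), rule_form = character(0),
        support = numeric(0), confidence = numeric(0), lift = numeric(0),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        lhs_items = vapply(rows, `[[`, "", "lhs"),
        rhs_item = vapply(rows, `[[`, "", "rhs"),
        rule_form = vapply(rows, `[[`, "", "form"),
        support = vapply(rows, `[[`, 0, "support"),
        confidence = vapply(rows, `[[`, 0, "confidence"),
        lift = vapply(rows, `[[`, 0, "lift"),
        stringsAsFactors = FALSE
      )
    }
  }
  ord <- order(match(out$rule_form, .rule_forms), out$lhs_items, out$rhs_item,
    method = "radix"
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_strains_mined") <- nrow(X)
  attr(out, "thresholds") <- thr
  class(out) <- c("rule_set", "data.frame")
  out
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf(
    "rule set: %d rules (%s) mined over %s strains\n",
    nrow(x), paste(names(table(x$rule_form)), table(x$rule_form),
      sep = ": ", collapse = ", "
    ),
    attr(x, "n_strains_mined") %||% "?"
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
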