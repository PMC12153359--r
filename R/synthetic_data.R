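#' Study-like prevalence spectrum
#'
#' 76 per-virus marginal probabilities log-spaced between 1/405 and 0.8,
#' emulating a virome survey in which one virus is near-ubiquitous (the most
#' common one was found in about 80% of strains) while several occur in a
#' single strain. The long low-prevalence tail deliberately stresses the
#' low-support strata of the calibration.
#'
#' @param n_viruses number of viruses (default 76).
#' @param n_strains cohort size anchoring the rarest prevalence (default 405).
#' @param max_prevalence upper end of the spectrum (default 0.8).
#' @return a numeric vector of probabilities.
#' @export
default_prevalence <- function(n_viruses = 76L, n_strains = 405L, max_prevalence = 0.8) {
  exp(seq(log(1 / n_strains), log(max_prevalence), length.out = n_viruses))
}

#' Synthetic cohort configuration
#'
#' Describes the generative world for a presence/absence matrix: cohort
#' size, per-virus marginal prevalences, and (optionally) planted pairwise
#' and conditional dependencies that the mining pipeline should recover.
#' A planted pair `(A, B, p_b_given_a, p_b_given_nota)` makes virus B's
#' occurrence depend on A's; a planted conditional
#' `(A, B, C, cpt)` gives virus C a probability for each of the four (A, B)
#' states (`cpt` named `c("FF", "FT", "TF", "TT")`, states ordered A then B).
#' The planted dependency graph must be acyclic so a generation order exists.
#'
#' @param n_strains,n_viruses cohort dimensions (defaults 405 x 76, the
#'   scale of the survey this generator stands in for).
#' @param prevalence per-virus marginal probabilities for viruses without a
#'   planted parent (default [default_prevalence()]).
#' @param planted_pairs list of lists with fields `a`, `b`, `p_b_given_a`,
#'   `p_b_given_nota` (virus indices or names).
#' @param planted_conditionals list of lists with fields `a`, `b`, `c`,
#'   `cpt`.
#' @param seed master seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 405L, n_viruses = 76L,
                             prevalence = default_prevalence(n_viruses, n_strains),
                             planted_pairs = list(),
                             planted_conditionals = list(),
                             seed = 1L) {
  if (length(prevalence) != n_viruses) .stopf("prevalence must have one entry per virus")
  if (any(prevalence < 0 | prevalence > 1)) .stopf("prevalences must lie in [0, 1]")
  structure(
    list(
      n_strains = as.integer(n_strains), n_viruses = as.integer(n_viruses),
      prevalence = prevalence, planted_pairs = planted_pairs,
      planted_conditionals = planted_conditionals, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

.virus_names <- function(n) sprintf("V%02d", seq_len(n))

.strain_names <- function(n) sprintf("S%03d", seq_len(n))

.as_virus_index <- function(v, vn) {
  if (is.character(v)) {
    i <- match(v, vn)
    if (is.na(i)) .stopf("unknown virus id: %s", v)
    i
  } else {
    as.integer(v)
  }
}

#' Generate a matrix of mutually independent viruses
#'
#' Every cell is an independent Bernoulli draw with its column's prevalence;
#' any planted structure in the config is ignored. This is the ground-truth
#' null world for false-positive-rate checks: any rule mined from it is a
#' false positive.
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a [pa_matrix()].
#' @export
generate_null_matrix <- function(config = synthetic_config(), seed = NULL) {
  seed <- seed %||% config$seed
  n <- config$n_strains
  V <- config$n_viruses
  X <- .with_seed(seed, {
    matrix(
      as.integer(stats::runif(n * V) < rep(config$prevalence, each = n)),
      n, V
    )
  })
  dimnames(X) <- list(.strain_names(n), .virus_names(V))
  pa_matrix(X)
}

# Topological generation order over the planted dependency graph
# (edges parent -> child); cycles are an error.
.generation_order <- function(n_viruses, edges) {
  indeg <- integer(n_viruses)
  adj <- vector("list", n_viruses)
  for (e in edges) {
    for (p in e$parents) {
      adj[[p]] <- c(adj[[p]], e$child)
      indeg[e$child] <- indeg[e$child] + 1L
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != n_viruses) .stopf("planted dependency graph has a cycle")
  order
}

#' Generate a matrix with planted dependencies
#'
#' Viruses are sampled in topological order of the planted graph. A virus
#' without a planted parent is Bernoulli at its marginal prevalence; the
#' child of a planted pair is Bernoulli(`p_b_given_a`) where the parent is
#' present and Bernoulli(`p_b_given_nota`) elsewhere; the child of a planted
#' conditional draws from its 4-entry conditional probability table on the
#' (A, B) states. A virus may be the child of at most one planted
#' dependency.
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a list: `matrix` (a [pa_matrix()]) and `truth` (a data frame
#'   describing each planted dependency, including the expected lift of the
#'   presence->presence rule implied by the plant).
#' @export
generate_planted_matrix <- function(config = synthetic_config(), seed = NULL) {
  seed <- seed %||% config$seed
  n <- config$n_strains
  V <- config$n_viruses
  vn <- .virus_names(V)
  pairs <- lapply(config$planted_pairs, function(p) {
    list(
      a = .as_virus_index(p$a, vn), b = .as_virus_index(p$b, vn),
      p_b_given_a = p$p_b_given_a, p_b_given_nota = p$p_b_given_nota
    )
  })
  conds <- lapply(config$planted_conditionals, function(p) {
    stopifnot(all(c("FF", "FT", "TF", "TT") %in% names(p$cpt)))
    list(
      a = .as_virus_index(p$a, vn), b = .as_virus_index(p$b, vn),
      c = .as_virus_index(p$c, vn), cpt = p$cpt
    )
  })
  children <- c(
    vapply(pairs, `[[`, 0L, "b"),
    vapply(conds, function(x) x$c, 0L)
  )
  if (anyDuplicated(children)) .stopf("a virus may be the child of only one planted dependency")
  edges <- c(
    lapply(pairs, function(p) list(parents = p$a, child = p$b)),
    lapply(conds, function(p) list(parents = c(p$a, p$b), child = p$c))
  )
  ord <- .generation_order(V, edges)
  pair_of <- conds_of <- vector("list", V)
  for (p in pairs) pair_of[[p$b]] <- p
  for (p in conds) conds_of[[p$c]] <- p

  X <- matrix(0L, n, V, dimnames = list(.strain_names(n), vn))
  .with_seed(seed, {
    for (v in ord) {
      if (!is.null(pair_of[[v]])) {
        p <- pair_of[[v]]
        prob <- ifelse(X[, p$a] == 1L, p$p_b_given_a, p$p_b_given_nota)
      } else if (!is.null(conds_of[[v]])) {
        p <- conds_of[[v]]
        state <- paste0(
          ifelse(X[, p$a] == 1L, "T", "F"),
          ifelse(X[, p$b] == 1L, "T", "F")
        )
        prob <- unname(unlist(p$cpt)[state])
      } else {
        prob <- config$prevalence[v]
      }
      X[, v] <- as.integer(stats::runif(n) < prob)
    }
  })

  truth_rows <- lapply(pairs, function(p) {
    pa <- .marginal_prevalence(p$a, pair_of, conds_of, config)
    pb <- pa * p$p_b_given_a + (1 - pa) * p$p_b_given_nota
    data.frame(
      kind = "pair", a = vn[p$a], b = vn[p$b], c = NA_character_,
      p_child_given_parent = p$p_b_given_a, p_child_given_noparent = p$p_b_given_nota,
      expected_lift_tt = if (pb > 0) p$p_b_given_a / pb else NA_real_,
      direction = if (p$p_b_given_a >= p$p_b_given_nota) "positive" else "negative",
      stringsAsFactors = FALSE
    )
  })
  truth_cond <- lapply(conds, function(p) {
    data.frame(
      kind = "conditional", a = vn[p$a], b = vn[p$b], c = vn[p$c],
      p_child_given_parent = p$cpt[["TT"]], p_child_given_noparent = p$cpt[["FF"]],
      expected_lift_tt = NA_real_,
      direction = if (p$cpt[["TT"]] >= p$cpt[["FF"]]) "positive" else "negative",
      stringsAsFactors = FALSE
    )
  })
  truth <- do.call(rbind, c(truth_rows, truth_cond)) %||% data.frame()
  list(matrix = pa_matrix(X), truth = truth)
}

# Marginal prevalence of a virus under the generative model; exact for
# root viruses and for children of a single planted pair rooted at a root.
.marginal_prevalence <- function(v, pair_of, conds_of, config) {
  if (!is.null(pair_of[[v]])) {
    p <- pair_of[[v]]
    pa <- .marginal_prevalence(p$a, pair_of, conds_of, config)
    pa * p$p_b_given_a + (1 - pa) * p$p_b_given_nota
  } else if (!is.null(conds_of[[v]])) {
    # upper-level marginals assumed independent for this summary
    p <- conds_of[[v]]
    pa <- .marginal_prevalence(p$a, pair_of, conds_of, config)
    pb <- .marginal_prevalence(p$b, pair_of, conds_of, config)
    pa * pb * p$cpt[["TT"]] + pa * (1 - pb) * p$cpt[["TF"]] +
      (1 - pa) * pb * p$cpt[["FT"]] + (1 - pa) * (1 - pb) * p$cpt[["FF"]]
  } else {
    config$prevalence[v]
  }
}

#' Lineage simulation configuration
#'
#' Models the uneven passage of co-infecting viruses into conidia: each
#' offspring keeps each parental virus independently with probability
#' `retention_prob`, after which any planted incompatible pair still jointly
#' present is resolved by dropping one member uniformly at random. Offspring
#' never gain viruses the parent lacks.
#'
#' @param n_offspring offspring per parent (default 10, the scale of the
#'   single-spore isolations in the validation experiment).
#' @param retention_prob per-virus retention probability (default 0.8).
#' @param incompatible_pairs list of 2-element character vectors of virus
#'   ids that cannot co-occur in an offspring.
#' @param seed integer seed.
#' @return a list of class `lineage_config`.
#' @export
lineage_config <- function(n_offspring = 10L, retention_prob = 0.8,
                           incompatible_pairs = list(), seed = 1L) {
  if (retention_prob < 0 || retention_prob > 1) .stopf("retention_prob must lie in [0, 1]")
  structure(
    list(
      n_offspring = as.integer(n_offspring), retention_prob = retention_prob,
      incompatible_pairs = incompatible_pairs, seed = as.integer(seed)
    ),
    class = "lineage_config"
  )
}

#' Simulate offspring virus compositions for a parent strain
#'
#' @param parent_viruses character vector of the parent's viruses (or a
#'   named 0/1 row of a [pa_matrix()]).
#' @param config a [lineage_config()].
#' @param parent_id id for the generated lineage.
#' @param origin lineage origin label.
#' @return a [lineage()].
#' @export
generate_lineages <- function(parent_viruses, config = lineage_config(),
                              parent_id = "synthetic_parent",
                              origin = "single_spore") {
  if (!is.character(parent_viruses)) {
    parent_viruses <- names(parent_viruses)[parent_viruses == 1L]
  }
  if (length(parent_viruses) == 0L) .stopf("parent carries no viruses")
  offspring <- .with_seed(config$seed, {
    lapply(seq_len(config$n_offspring), function(i) {
      kept <- parent_viruses[stats::runif(length(parent_viruses)) < config$retention_prob]
      for (pair in config$incompatible_pairs) {
        if (all(pair %in% kept)) {
          kept <- setdiff(kept, sample(pair, 1L))
        }
      }
      kept
    })
  })
  names(offspring) <- sprintf("%s_off%02d", parent_id, seq_len(config$n_offspring))
  lineage(parent_id, parent_viruses, offspring, origin = origin)
}

#' Write lineages to the CSV interchange format
#'
#' @param lineages a list of [lineage()] objects.
#' @param path output CSV path.
#' @export
write_lineages <- function(lineages, path) {
  if (inherits(lineages, "lineage")) lineages <- list(lineages)
  rows <- list()
  for (ln in lineages) {
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = ln$parent_id, member_id = ln$parent_id, role = "parent",
      viruses = paste(ln$parent_viruses, collapse = ";"), stringsAsFactors = FALSE
    )
    for (i in seq_along(ln$offspring)) {
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = ln$parent_id, member_id = names(ln$offspring)[i], role = "offspring",
        viruses = paste(ln$offspring[[i]], collapse = ";"), stringsAsFactors = FALSE
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
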