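# Shared fixtures, built in code.

# 10-strain, 2-virus worked example: A present in strains 1-5, B in 1-4.
toy_matrix <- function() {
  X <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), c("A", "B")))
  X[1:5, "A"] <- 1L
  X[1:4, "B"] <- 1L
  pa_matrix(X)
}

# Exact-independence construction: P(A) = 0.5, P(B) = 0.6, P(A and B) = 0.3.
independence_matrix <- function() {
  X <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), c("A", "B")))
  X[1:5, "A"] <- 1L
  X[c(1:3, 6:8), "B"] <- 1L
  pa_matrix(X)
}

random_pa_matrix <- function(n_strains, n_viruses, seed, p_range = c(0.15, 0.85)) {
  set.seed(seed)
  p <- runif(n_viruses, p_range[1], p_range[2])
  X <- matrix(
    as.integer(runif(n_strains * n_viruses) < rep(p, each = n_strains)),
    n_strains, n_viruses,
    dimnames = list(paste0("s", seq_len(n_strains)), paste0("v", seq_len(n_viruses)))
  )
  pa_matrix(X)
}
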