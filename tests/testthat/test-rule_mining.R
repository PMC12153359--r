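test_that("itemset support counts satisfying strains, with contradictions at 0", {
  m <- toy_matrix()
  expect_equal(itemset_support(m, c("A=T", "B=T")), 0.4)
  expect_equal(itemset_support(m, c("A=F", "B=F")), 0.5)
  expect_equal(itemset_support(m, c("A=T", "A=F")), 0)
  expect_equal(itemset_support(m, "A=T"), 0.5)
  expect_error(itemset_support(m, "Z=T"), "unknown virus")

  # agrees with direct counting on random matrices and itemsets
  for (s in 1:5) {
    mm <- random_pa_matrix(30, 6, seed = 100 + s)
    set.seed(200 + s)
    items <- paste0(sample(colnames(mm), 3), "=", sample(c("T", "F"), 3, replace = TRUE))
    expect_equal(itemset_support(mm, items), bf_support(mm, items))
  }
})

test_that("rule metrics implement Support, Confidence and Lift", {
  m <- toy_matrix()
  r <- compute_rule_metrics(m, "A=T", "B=T")
  expect_equal(r$support, 0.4)
  expect_equal(r$confidence, 0.8)
  expect_equal(r$lift, 2.0)
  r2 <- compute_rule_metrics(m, "A=F", "B=F")
  expect_equal(r2$support, 0.5)
  expect_equal(r2$confidence, 1.0)
  expect_equal(r2$lift, 5 / 3)
  # exact independence gives lift 1
  expect_equal(compute_rule_metrics(independence_matrix(), "A=T", "B=T")$lift, 1.0)
  # zero-support sides are an error, not a silent NaN
  z <- pa_matrix(matrix(c(1L, 1L, 0L, 0L), 2, 2,
    dimnames = list(c("s1", "s2"), c("A", "B"))
  ))
  expect_error(compute_rule_metrics(z, "A=F", "B=T"), "undefined metric")
  expect_error(compute_rule_metrics(m, "A=T", "A=F"), "also appears")
})

test_that("a 2-virus matrix with all state pairs attainable yields 8 one-to-one rules", {
  r <- enumerate_candidate_rules(
    independence_matrix(),
    mining_config(1, 0, 0, mined_strains = "all")
  )
  expect_equal(nrow(r), 8L)
  expect_true(all(r$rule_form == "one_to_one"))
  # ordered rules: both directions present
  expect_true("A=T" %in% r$lhs_items && "A=T" %in% r$rhs_item)
})

test_that("enumeration is deterministic and canonically ordered", {
  m <- random_pa_matrix(40, 8, seed = 42)
  cfg <- mining_config(2, 0.05, 0.05, "all")
  r1 <- enumerate_candidate_rules(m, cfg)
  r2 <- enumerate_candidate_rules(m, cfg)
  expect_identical(r1$lhs_items, r2$lhs_items)
  expect_identical(r1$lift, r2$lift)
  ord <- order(match(r1$rule_form, c("one_to_one", "two_to_one", "three_to_one")),
    r1$lhs_items, r1$rhs_item,
    method = "radix"
  )
  expect_identical(ord, seq_len(nrow(r1)))
})

test_that("support is anti-monotone in the itemset", {
  for (s in 1:10) {
    m <- random_pa_matrix(25, 5, seed = 300 + s)
    set.seed(400 + s)
    vs <- sample(colnames(m), 3)
    base <- paste0(vs[1:2], "=", sample(c("T", "F"), 2, replace = TRUE))
    extra <- paste0(vs[3], "=", sample(c("T", "F"), 1))
    expect_lte(
      itemset_support(m, c(base, extra)),
      itemset_support(m, base)
    )
  }
})

test_that("lift and support are symmetric under rule reversal; confidence is not forced to be", {
  m <- random_pa_matrix(50, 6, seed = 77)
  r <- enumerate_candidate_rules(m, mining_config(1, 0.02, 0.02, "all"))
  key_fwd <- paste(r$lhs_items, r$rhs_item)
  key_rev <- paste(r$rhs_item, r$lhs_items)
  idx <- match(key_rev, key_fwd)
  present <- !is.na(idx)
  expect_gt(sum(present), 0)
  expect_equal(r$lift[present], r$lift[idx[present]], tolerance = 1e-12)
  expect_equal(r$support[present], r$support[idx[present]], tolerance = 1e-12)
})

test_that("mining probabilities come from the mined strain subset", {
  # deleting a strain satisfying neither item of the pair changes only the
  # denominator: joint and antecedent counts are untouched
  m <- toy_matrix() # strain s10 has neither A nor B
  keep <- rownames(m) != "s10"
  m_del <- pa_matrix(unclass(m)[keep, ])
  a <- compute_rule_metrics(m, "A=T", "B=T")
  b <- compute_rule_metrics(m_del, "A=T", "B=T")
  expect_equal(b$support, 4 / 9)
  expect_equal(b$confidence, a$confidence) # antecedent count unchanged
  # virus-free strains (s6..s10 in the toy matrix) are excluded by default
  r_masked <- enumerate_candidate_rules(toy_matrix(), mining_config(1, 0, 0))
  expect_equal(attr(r_masked, "n_strains_mined"), 5L)
  r_all <- enumerate_candidate_rules(toy_matrix(), mining_config(1, 0, 0, "all"))
  expect_equal(attr(r_all, "n_strains_mined"), 10L)
  # default thresholds resolve to 3/V
  thr <- attr(enumerate_candidate_rules(random_pa_matrix(20, 6, 5), mining_config(1)), "thresholds")
  expect_equal(thr$min_support, 3 / 6)
})

test_that("the Apriori miner matches the brute-force oracle on small matrices", {
  for (s in 1:8) {
    set.seed(500 + s)
    V <- sample(3:6, 1)
    n <- sample(12:40, 1)
    max_lhs <- sample(1:3, 1)
    min_s <- sample(c(0, 3 / V, 0.1), 1)
    min_c <- sample(c(0, 0.2), 1)
    m <- random_pa_matrix(n, V, seed = 600 + s)
    got <- enumerate_candidate_rules(m, mining_config(max_lhs, min_s, min_c, "all"))
    want <- bf_enumerate(m, max_lhs, min_s, min_c)
    expect_equal(nrow(got), nrow(want), info = sprintf("case %d", s))
    expect_identical(got$lhs_items, want$lhs_items)
    expect_identical(got$rhs_item, want$rhs_item)
    expect_equal(got$support, want$support, tolerance = 1e-12)
    expect_equal(got$confidence, want$confidence, tolerance = 1e-12)
    expect_equal(got$lift, want$lift, tolerance = 1e-12)
  }
})
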