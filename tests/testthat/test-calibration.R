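test_that("column permutation preserves prevalences and is seed-deterministic", {
  m <- random_pa_matrix(50, 10, seed = 1)
  p1 <- permute_matrix_columns(m, seed = 9)
  expect_equal(colSums(unclass(p1)), colSums(unclass(m)))
  expect_identical(unclass(permute_matrix_columns(m, seed = 9)), unclass(p1))
  expect_false(identical(unclass(permute_matrix_columns(m, seed = 10)), unclass(p1)))
  # a single-strain matrix cannot change
  one <- pa_matrix(matrix(c(1L, 0L), 1, 2, dimnames = list("s1", c("A", "B"))))
  expect_identical(unclass(permute_matrix_columns(one, seed = 3)), unclass(one))
})

test_that("the pooled null is deterministic and centred near lift 1", {
  m <- random_pa_matrix(200, 10, seed = 2, p_range = c(0.3, 0.7))
  cfg <- mining_config(1, 0.02, 0.02, "all")
  cc <- calibration_config(n_permutations = 30, seed = 5)
  pool1 <- build_null_lift_distribution(m, cfg, cc)
  pool2 <- build_null_lift_distribution(m, cfg, cc)
  expect_identical(pool1$lift, pool2$lift)
  # independence null: lifts concentrate around 1
  expect_lt(abs(stats::median(pool1$lift) - 1), 0.05)
  expect_error(
    build_null_lift_distribution(m, cfg, calibration_config(n_permutations = 0)),
    "empty null"
  )
})

test_that("stratum thresholds are the documented type-7 empirical quantile", {
  # constant null: threshold equals the constant
  pool <- data.frame(support = rep(0.5, 100), confidence = rep(0.5, 100), lift = rep(1.0, 100))
  cc <- calibration_config(alpha = 0.05, support_bins = c(0, 1), confidence_bins = c(0, 1))
  tab <- calibrate_dynamic_thresholds(pool, cc)
  expect_equal(tab$strata$lift_threshold, 1.0)

  # lifts 0.01..1.00: hand-computed type-7 0.95-quantile is 0.9505
  pool2 <- data.frame(
    support = rep(0.5, 100), confidence = rep(0.5, 100),
    lift = (1:100) * 0.01
  )
  tab2 <- calibrate_dynamic_thresholds(pool2, cc)
  expect_equal(tab2$strata$lift_threshold, 0.9505)

  # strata with no null rules fall back to the global quantile and are flagged
  cc3 <- calibration_config(alpha = 0.05, support_bins = c(0, 0.5, 1), confidence_bins = c(0, 1))
  tab3 <- calibrate_dynamic_thresholds(pool2, cc3) # all nulls in the [0.5,1] support bin
  expect_true(tab3$strata$fallback[tab3$strata$support_bin == 1])
  expect_equal(
    tab3$strata$lift_threshold[tab3$strata$support_bin == 1],
    tab3$global_threshold
  )
  expect_false(tab3$strata$fallback[tab3$strata$support_bin == 2])
})

test_that("filtering is strict at the threshold and records it", {
  pool <- data.frame(support = rep(0.5, 100), confidence = rep(0.5, 100), lift = rep(1.0, 100))
  cc <- calibration_config(support_bins = c(0, 1), confidence_bins = c(0, 1))
  tab <- calibrate_dynamic_thresholds(pool, cc)
  cand <- data.frame(
    lhs_items = c("A=T", "B=T"), rhs_item = c("B=T", "A=T"),
    rule_form = "one_to_one",
    support = c(0.4, 0.4), confidence = c(0.8, 0.8), lift = c(1.0, 1.2)
  )
  kept <- filter_significant_rules(cand, tab)
  expect_equal(nrow(kept), 1L) # lift exactly at threshold is rejected
  expect_equal(kept$lift, 1.2)
  expect_equal(kept$lift_threshold_applied, 1.0)
  expect_equal(attr(kept, "n_candidates"), 2L)
  # published-style global floors
  expect_equal(nrow(filter_significant_rules(cand, tab, min_lift = 1.3)), 0L)
  expect_equal(nrow(filter_significant_rules(cand, tab, min_support = 0.45)), 0L)
})

test_that("raising alpha never shrinks the retained set", {
  m <- random_pa_matrix(150, 12, seed = 31, p_range = c(0.2, 0.8))
  cfg <- mining_config(1)
  cand <- enumerate_candidate_rules(m, cfg)
  pool <- build_null_lift_distribution(m, cfg, calibration_config(n_permutations = 40, seed = 8))
  n_kept <- vapply(c(0.01, 0.05, 0.2, 0.5), function(a) {
    cc <- calibration_config(alpha = a, n_permutations = 40, seed = 8)
    nrow(filter_significant_rules(cand, calibrate_dynamic_thresholds(pool, cc)))
  }, 0)
  expect_true(all(diff(n_kept) >= 0))
})

test_that("calibration tables serialize to JSON and back", {
  pool <- data.frame(
    support = runif(200, 0, 0.6), confidence = runif(200, 0, 1),
    lift = rlnorm(200, 0, 0.2)
  )
  tab <- calibrate_dynamic_thresholds(pool, calibration_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_table(tab, path)
  back <- read_calibration_table(path)
  expect_equal(back$global_threshold, tab$global_threshold)
  expect_equal(back$support_bins, tab$support_bins)
  expect_equal(back$strata$lift_threshold, tab$strata$lift_threshold)
})
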