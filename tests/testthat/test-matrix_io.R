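test_that("wide and long presence matrices round-trip and validate", {
  m <- toy_matrix()
  wide <- withr::local_tempfile(fileext = ".csv")
  write_presence_matrix(m, wide)
  m2 <- read_presence_matrix(wide, "wide")
  expect_identical(unclass(m2), unclass(m))

  # long format lists only present pairs; unlisted pairs default to absent
  long <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    strain_id = c("s1", "s1", "s2", "s3"),
    virus_id = c("A", "B", "A", "B"),
    present = 1L
  )
  write.csv(df, long, row.names = FALSE)
  m3 <- read_presence_matrix(long, "long")
  expect_equal(dim(m3), c(3L, 2L))
  expect_equal(unname(unclass(m3)["s2", ]), c(1L, 0L))
  expect_equal(unname(unclass(m3)["s3", ]), c(0L, 1L))

  # duplicate long entries are an error
  dup <- rbind(df, df[1, ])
  write.csv(dup, long, row.names = FALSE)
  expect_error(read_presence_matrix(long, "long"), "duplicate entry")
})

test_that("invalid cells and duplicate strain ids are rejected with locations", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("strain_id,A,B", "s1,1,0", "s2,2,1"), bad)
  expect_error(read_presence_matrix(bad, "wide"), "invalid value.*s2.*A")
  writeLines(c("strain_id,A,B", "s1,1,0", "s1,0,1"), bad)
  expect_error(read_presence_matrix(bad, "wide"), "duplicate strain id")
  expect_error(
    pa_matrix(matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("v", "v")))),
    "duplicate virus id"
  )
})

test_that("cohort summary bins co-infection counts into a partition", {
  # all-zero virome: every strain in the 0 bin
  z <- pa_matrix(matrix(0L, 5, 4, dimnames = list(paste0("s", 1:5), paste0("v", 1:4))))
  cs <- cohort_summary(z)
  expect_equal(unname(cs$histogram["0"]), 5L)
  expect_equal(sum(cs$histogram), 5L)

  # bins partition any cohort; prevalence counts ignore row/column order
  m <- random_pa_matrix(60, 30, seed = 11)
  cs <- cohort_summary(m)
  expect_equal(sum(cs$histogram), 60L)
  expect_true(all(cs$virus_counts <= 60L))
  shuffled <- pa_matrix(unclass(m)[sample(60), sample(30)])
  cs2 <- cohort_summary(shuffled)
  expect_equal(sort(unname(cs2$virus_counts)), sort(unname(cs$virus_counts)))
  expect_equal(cs2$histogram, cs$histogram)

  # bin edges follow the reporting convention {0,1,2,3-5,6-10,11-15,16-20,>=21}
  counts <- c(0, 1, 2, 3, 5, 6, 10, 11, 15, 16, 20, 21, 25)
  X <- matrix(0L, length(counts), 25,
    dimnames = list(paste0("s", seq_along(counts)), paste0("v", 1:25))
  )
  for (i in seq_along(counts)) if (counts[i] > 0) X[i, seq_len(counts[i])] <- 1L
  h <- cohort_summary(pa_matrix(X))$histogram
  expect_equal(
    unname(h),
    c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L)
  )
})

test_that("lineage files parse, validate the vocabulary, and flag empty lineages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "parent_id,member_id,role,viruses",
    "P1,P1,parent,A;B;C",
    "P1,P1_o1,offspring,A;B",
    "P1,P1_o2,offspring,C",
    "P2,P2,parent,A",
    "P3,P3,parent,B;C"
  ), f)
  ln <- read_lineages(f, vocabulary = c("A", "B", "C"))
  expect_length(ln, 3L)
  expect_length(ln$P1$offspring, 2L)
  expect_true(ln$P1$usable)
  expect_false(ln$P3$usable) # no offspring: unusable for validation

  writeLines(c(
    "parent_id,member_id,role,viruses",
    "P1,P1,parent,A;X"
  ), f)
  expect_error(read_lineages(f, vocabulary = c("A", "B")), "unknown virus id.*X")
})

test_that("rule tables round-trip losslessly, including the empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(
    lhs_items = character(0), rhs_item = character(0), rule_form = character(0),
    support = numeric(0), confidence = numeric(0), lift = numeric(0)
  )
  write_rules_table(empty, path)
  expect_equal(nrow(read_rules_table(path)), 0L)
  expect_equal(length(readLines(path)), 1L) # header only

  one <- data.frame(
    lhs_items = "A=T", rhs_item = "B=T", rule_form = "one_to_one",
    support = 0.4, confidence = 0.8, lift = 2.0,
    stringsAsFactors = FALSE
  )
  write_rules_table(one, path)
  back <- read_rules_table(path)
  expect_equal(back$lhs_items, "A=T")
  expect_equal(back$support, 0.4)
  expect_equal(back$confidence, 0.8)
  expect_equal(back$lift, 2.0)
  expect_true(is.na(back$rule_type))
})
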