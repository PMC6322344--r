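test_that("cohort CSV round trip preserves records and validation rejects bad levels", {
  coh <- as_cohort(tiny_cohort_df())
  expect_s3_class(coh, "caries_cohort")
  expect_equal(nrow(coh), 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh)

  bad <- tiny_cohort_df()
  bad$gender[2] <- "M"
  expect_error(as_cohort(bad), "row 2.*gender|gender.*row 2")
  bad2 <- tiny_cohort_df()
  bad2$outcome[3] <- ""
  expect_error(as_cohort(bad2), "outcome.*row 3")
  expect_error(as_cohort(tiny_cohort_df()[, -2]), "missing column")
})

test_that("age-group spelling variants and case are normalized at read time", {
  df <- tiny_cohort_df()
  df$age_group <- c("<=18", "18–25", "> = 35")  # en dash, spaced
  df$gender <- c("FEMALE", "male", "Male")
  coh <- as_cohort(df)
  expect_equal(as.character(coh$age_group), c("<18", "18-25", ">=35"))
  expect_equal(as.character(coh$gender), c("Female", "Male", "Male"))
})

test_that("reference coding yields the fixed 8-slot design", {
  all_ref <- data.frame(outcome = 1, gender = "Female", residence = "Urban",
                        region = "Others", age_group = "<18", clean_teeth = "No")
  all_non <- data.frame(outcome = 0, gender = "Male", residence = "Rural",
                        region = "SNNPR", age_group = "18-25", clean_teeth = "Yes")
  d <- encode_design(as_cohort(rbind(all_ref, all_non)))
  expect_equal(colnames(d$X), design_slots())
  expect_equal(unname(d$X[1, ]), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(d$X[2, ]), c(1, 1, 1, 1, 1, 0, 0, 1))
  expect_equal(unname(colSums(d$X)), c(2, 1, 1, 1, 1, 0, 0, 1))
  # every row sums to 1 (intercept) + number of non-reference memberships
  coh <- generate_cohort(generator_config(n = 200, seed = 7))
  D <- encode_design(coh)
  nonref <- (coh$gender != "Female") + (coh$residence != "Urban") +
    (coh$region != "Others") + (coh$age_group != "<18") + (coh$clean_teeth != "No")
  expect_equal(unname(rowSums(D$X)), unname(1 + nonref))
})

test_that("cross-tabulation counts partition the cohort and percentages are row-wise", {
  coh <- generate_cohort(generator_config(n = 500, seed = 3))
  for (cv in c("gender", "residence", "region", "age_group", "clean_teeth")) {
    ct <- cross_tabulate(coh, cv)
    expect_equal(sum(ct$count_nonnatural + ct$count_natural), nrow(coh))
    expect_equal(ct$pct_natural + ct$pct_nonnatural,
                 rep(100, nrow(ct)))
  }
  one <- cross_tabulate(as_cohort(tiny_cohort_df()[1, ]), "gender")
  expect_equal(one$count_natural[one$level == "Female"], 1)
  expect_equal(one$pct_natural[one$level == "Female"], 100)
  expect_error(cross_tabulate(coh, "diet"), "unknown covariate")
})

test_that("reconstructed clinic cohort reproduces every published cross-tab row", {
  coh <- reconstruct_cohort()
  expect_equal(nrow(coh), 6007)
  counts <- clinic_crosstab_counts()
  for (cv in unique(counts$covariate)) {
    ct <- cross_tabulate(coh, cv)
    ref <- counts[counts$covariate == cv, ]
    ref <- ref[match(ct$level, ref$level), ]
    expect_equal(ct$count_nonnatural, ref$nonnatural)
    expect_equal(ct$count_natural, ref$natural)
  }
  gender <- cross_tabulate(coh, "gender")
  expect_equal(round(gender$pct_natural[gender$level == "Female"], 1), 88.4)
})

test_that("crude odds and risk ratios match the 2x2 formulas and zero-cell policy", {
  expect_equal(crude_odds_ratio(1, 1, 1, 1), 1.0)
  expect_equal(crude_risk_ratio(1, 1, 1, 1), 1.0)
  expect_equal(crude_odds_ratio(327, 2501, 451, 2728),
               (2728 * 327) / (451 * 2501))
  expect_equal(crude_risk_ratio(327, 2501, 451, 2728),
               (2728 / 3179) / (2501 / 2828))
  expect_error(crude_odds_ratio(5, 0, 5, 5), "zero cell 'b'")
  expect_error(crude_risk_ratio(5, 0, 5, 5), "zero cell")
  expect_error(crude_odds_ratio(-1, 1, 1, 1), "negative")
  # Haldane-Anscombe correction is explicit, never silent
  expect_equal(crude_odds_ratio(5, 0, 5, 5, correct = TRUE),
               (5.5 * 5.5) / (0.5 * 5.5))
})

test_that("the odds ratio is never closer to the null than the risk ratio", {
  # brute force over all 2x2 tables with cells 1..6
  for (a in 1:6) for (b in 1:6) for (c in 1:6) for (d in 1:6) {
    or <- crude_odds_ratio(a, b, c, d)
    rr <- crude_risk_ratio(a, b, c, d)
    expect_gte(abs(log(or)), abs(log(rr)) - 1e-12)
  }
})
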