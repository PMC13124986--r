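test_that("suicide labelling matches PT lists and generator recount", {
  reac <- data.table::data.table(
    primaryid = c(1, 1, 2, 3),
    pt = c("Nausea", "SUICIDAL IDEATION", "Nausea", "suicide attempt "))
  lab <- label_suicide_reports(reac, pv_suicide_pts())
  expect_identical(lab$suicide, c(TRUE, FALSE, TRUE))
  expect_error(label_suicide_reports(reac, character(0)), "non-empty")

  # brute-force recount on the simulated canonical reports
  sh <- shared_sim()
  demo <- deduplicate(sh$sim$tables$demo)
  reac_all <- data.table::as.data.table(sh$sim$tables$reac)[
    primaryid %in% demo$primaryid]
  lab2 <- label_suicide_reports(reac_all, pv_suicide_pts(),
                                ids = demo$primaryid)
  direct <- unique(reac_all[pt %in% pv_suicide_pts(), primaryid])
  expect_identical(sum(lab2$suicide), length(direct))
})

test_that("characterization reproduces printed cohort proportions", {
  # overall cohort: 8,332 female of 13,698 reports -> 60.83%
  reports <- data.table::data.table(
    primaryid = seq_len(13698),
    sex = rep(c("female", "male", NA), c(8332, 3639, 1727)))
  ch <- characterize_cohort(reports, keys = "sex")
  expect_equal(ch[category == "female", pct], 60.83)
  expect_equal(ch[category == "male", pct], 26.57)
  expect_equal(sum(ch$n), 13698)

  # suicide subset: 708 female of 1,273 -> 55.62%
  su <- data.table::data.table(
    primaryid = seq_len(1273),
    sex = rep(c("female", "male", NA), c(708, 459, 106)))
  ch2 <- characterize_cohort(su, keys = "sex")
  expect_equal(ch2[category == "female", pct], 55.62)

  # empty cohort: no category rows
  empty <- reports[0]
  expect_identical(nrow(characterize_cohort(empty, keys = "sex")), 0L)
  expect_error(characterize_cohort(reports, keys = "shoe_size"), "unknown")
})

test_that("demographic proportions conserve the cohort total", {
  sh <- shared_sim()
  d <- sim_to_dir(sh$sim)
  tabs <- read_faers_ascii(d)
  target <- select_target_reports(tabs$drug, pv_vortioxetine_synonyms())
  rec <- assemble_records(tabs, target)
  ch <- characterize_cohort(rec$reports, keys = c("sex", "age", "weight"))
  for (k in unique(ch$characteristic)) {
    expect_identical(sum(ch[characteristic == k, n]), nrow(rec$reports))
  }
})

test_that("subgroup tests reproduce the published contingency statistics", {
  sex <- matrix(c(7624, 708, 3180, 459), 2, 2, byrow = TRUE,
                dimnames = list(c("Female", "Male"), NULL))
  ts <- subgroup_test(sex)
  expect_equal(ts$statistic, 48.77, tolerance = 0.01 / 48.77)
  expect_lt(ts$p_value, 0.001)
  expect_identical(ts$test_used, "pearson")
  expect_identical(ts$df, 1L)

  age <- matrix(c(982, 109, 4102, 570, 965, 75, 86, 2), 4, 2, byrow = TRUE)
  ta <- subgroup_test(age)
  expect_equal(ta$statistic, 30.17, tolerance = 0.01 / 30.17)
  expect_identical(ta$df, 3L)

  wt <- matrix(c(157, 14, 1967, 202, 340, 40), 3, 2, byrow = TRUE)
  tw <- subgroup_test(wt)
  expect_equal(tw$statistic, 0.88, tolerance = 0.015)
  expect_equal(tw$p_value, 0.64, tolerance = 0.01)
})

test_that("test policy, degenerate rows and invariances", {
  # sparse table switches to Fisher under the auto policy
  sparse <- matrix(c(3, 2, 50, 60), 2, 2, byrow = TRUE)
  expect_identical(subgroup_test(sparse)$test_used, "fisher")
  expect_identical(subgroup_test(sparse, policy = "pearson")$test_used,
                   "pearson")
  # all-zero row dropped, df adjusted
  z <- matrix(c(50, 60, 0, 0, 40, 30), 3, 2, byrow = TRUE)
  expect_warning(tz <- subgroup_test(z, policy = "pearson"), "dropped")
  expect_identical(tz$df, 1L)
  # permutation invariance of rows
  m <- matrix(c(982, 109, 4102, 570, 965, 75, 86, 2), 4, 2, byrow = TRUE)
  t1 <- subgroup_test(m)
  t2 <- subgroup_test(m[c(3, 1, 4, 2), ])
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  # Pearson and Fisher agree on large balanced tables
  big <- matrix(c(2000, 1920, 2040, 2120), 2, 2, byrow = TRUE)
  pp <- subgroup_test(big, policy = "pearson")$p_value
  pf <- subgroup_test(big, policy = "fisher")$p_value
  expect_lt(abs(pp - pf), 0.01)
})

test_that("age re-binning respects boundary rules", {
  ages <- c(17.9, 18, 24.0, 24.1, 64.9, 65, 85, 85.1, NA)
  expect_identical(age_rebin(ages, "table6"),
                   c("<18", "18-64", "18-64", "18-64", "18-64", "65-85",
                     "65-85", ">85", NA))
  expect_identical(age_rebin(ages, "fda_warning"),
                   c("<=24", "<=24", "<=24", "25-64", "25-64", ">=65",
                     ">=65", ">=65", NA))
  # bin counts match a brute-force recount on simulated ages
  sh <- shared_sim()
  a <- sh$sim$truth$reports$age_years
  bins <- age_rebin(a, "table6")
  expect_identical(sum(bins == "<18", na.rm = TRUE),
                   sum(a < 18, na.rm = TRUE))
  expect_identical(sum(bins == "65-85", na.rm = TRUE),
                   sum(a >= 65 & a <= 85, na.rm = TRUE))
  expect_identical(sum(is.na(bins)), sum(is.na(a)))
})
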