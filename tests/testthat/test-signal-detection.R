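test_that("contingency cells have correct counts and conserved margins", {
  # toy cohort: 10 target reports, event seen in 4
  reac <- data.table::data.table(
    primaryid = c(1:4, 11:30),
    pt = c(rep("Nausea", 4), rep("Headache", 20)))
  cells <- build_cells(reac, target_ids = 1:10, background_ids = 1:40)
  nau <- cells[event == "Nausea"]
  expect_identical(c(nau$a, nau$b, nau$c, nau$d), c(4L, 6L, 0L, 30L))
  # margins: a + b = cohort size for every event; a + c = event total
  expect_true(all(cells$a + cells$b == 10L))
  expect_true(all(cells$N == 40L))
  expect_error(build_cells(reac, 1:10, integer(0)), "background")

  # on simulated data the planted pair's empirical rate ratio recovers
  sh <- shared_sim()
  truth <- sh$sim$truth$reports
  demo <- deduplicate(sh$sim$tables$demo)
  reac_all <- unique(data.table::as.data.table(
    sh$sim$tables$reac)[primaryid %in% demo$primaryid, .(primaryid, pt)])
  tgt <- as.numeric(truth[truth$is_target == TRUE, primaryid])
  cells <- build_cells(reac_all, tgt, demo$primaryid)
  pl <- cells[event == sh$sim$truth$event_names[28]]
  rr_hat <- (pl$a / (pl$a + pl$b)) / (pl$c / (pl$c + pl$d))
  expect_gt(rr_hat, 8 * 0.7)
  expect_lt(rr_hat, 8 * 1.3)
})

test_that("SOC-level cells count one contribution per report per SOC", {
  reac <- data.table::data.table(
    primaryid = c(1, 1, 1, 2, 21),
    pt = c("Nausea", "Vomiting", "Anxiety", "Nausea", "Anxiety"))
  cells <- build_cells(reac, target_ids = 1:10, background_ids = 1:40,
                       level = "SOC", pt_soc = pv_example_pt_soc())
  gi <- cells[event == "Gastrointestinal disorders"]
  # report 1 counts once despite two GI PTs
  expect_identical(gi$a, 2L)
  psych <- cells[event == "Psychiatric disorders"]
  expect_identical(c(psych$a, psych$c), c(1L, 1L))
  # unmapped PTs go to the sentinel SOC
  reac2 <- rbind(reac, data.table::data.table(primaryid = 3,
                                              pt = "Not a real PT"))
  expect_warning(
    cells2 <- build_cells(reac2, 1:10, 1:40, level = "SOC",
                          pt_soc = pv_example_pt_soc()),
    "UNMAPPED")
  expect_identical(cells2[event == "UNMAPPED"]$a, 1L)
})

test_that("ROR matches cross-ratio arithmetic with Woolf interval", {
  s <- ror_stats(10, 10, 10, 10)
  expect_equal(s$ror, 1)
  expect_lt(s$ror_lo95, 1)
  expect_gt(s$ror_hi95, 1)
  expect_equal(ror_stats(20, 80, 100, 9800)$ror, 24.5)
  # degenerate cell: undefined, never flagged
  s0 <- ror_stats(0, 100, 50, 9850)
  expect_true(is.na(s0$ror))
  # haldane policy defines it
  expect_false(is.na(ror_stats(0, 100, 50, 9850,
                               zero_policy = "haldane")$ror))
})

test_that("PRR and its chi-square match direct arithmetic and chisq.test", {
  expect_equal(prr_stats(20, 80, 100, 9800)$prr, 19.8)
  s <- prr_stats(10, 90, 100, 900)  # equal proportions
  expect_equal(s$prr, 1)
  expect_equal(s$prr_chisq, 0)
  # cross-check the vectorized Pearson formula against stats::chisq.test
  set.seed(42)
  for (i in 1:20) {
    cell <- rpois(4, c(15, 200, 300, 5000)) + 1
    m <- matrix(cell, 2, 2, byrow = TRUE)
    got <- prr_stats(cell[1], cell[2], cell[3], cell[4])$prr_chisq
    ref <- unname(suppressWarnings(
      chisq.test(m, correct = FALSE)$statistic))
    expect_equal(got, ref, tolerance = 1e-12)
    got_y <- prr_stats(cell[1], cell[2], cell[3], cell[4],
                       correction = TRUE)$prr_chisq
    ref_y <- unname(suppressWarnings(
      chisq.test(m, correct = TRUE)$statistic))
    expect_equal(got_y, ref_y, tolerance = 1e-12)
  }
})

test_that("null chi-square values are calibrated to the chi2(1) law", {
  # all relative rates 1: ~5% of cells should exceed the 95th percentile
  set.seed(7)
  n_t <- 2000; n_o <- 38000; p <- 0.03
  a <- rbinom(1000, n_t, p); c_ <- rbinom(1000, n_o, p)
  chisq <- prr_stats(a, n_t - a, c_, n_o - c_)$prr_chisq
  frac <- mean(chisq > qchisq(0.95, 1), na.rm = TRUE)
  expect_gt(frac, 0.025)
  expect_lt(frac, 0.085)
})

test_that("information component behaves at independence and deficit", {
  # exact independence point: a N = (a+b)(a+c)
  s <- bcpnn_stats(100, 900, 900, 8100)
  expect_lt(abs(s$ic), 0.05)
  # zero-count cell: point estimate undefined, credible bound negative
  s0 <- bcpnn_stats(0, 500, 2000, 47500)
  expect_true(is.na(s0$ic))
  expect_lt(s0$ic025, 0)
})

test_that("closed-form IC025 agrees with Monte-Carlo posterior sampling", {
  cells <- list(c(20, 80, 100, 9800), c(5, 95, 50, 9850),
                c(200, 1800, 3000, 55000))
  for (cl in cells) {
    cf <- bcpnn_stats(cl[1], cl[2], cl[3], cl[4])$ic025
    mc <- bcpnn_mc_quantile(cl[1], cl[2], cl[3], cl[4], n = 1e5, seed = 11)
    expect_lt(abs(cf - mc), 0.05)
  }
})

test_that("MGPS prior recovery on simulated rate ratios", {
  set.seed(31)
  n <- 2000
  E <- rgamma(n, 5, 0.5)
  # pure null: lambda concentrated at 1
  a_null <- rpois(n, rgamma(n, 40, 40) * E)
  p0 <- fit_mgps_prior(a_null, E)
  mean0 <- p0$P * p0$alpha1 / p0$beta1 + (1 - p0$P) * p0$alpha2 / p0$beta2
  expect_gt(mean0, 0.8)
  expect_lt(mean0, 1.25)

  expect_error(fit_mgps_prior(5, 2), "at least 2")
})

test_that("EBGM matches the numerical-integration posterior oracle", {
  prior <- make_prior(18, 1.8, 19, 19.4, 0.10)
  set.seed(5)
  E <- rgamma(20, 5, 0.5)
  a <- rpois(20, E * ifelse(runif(20) < 0.9, 1, 8))
  st <- mgps_stats(a, E, prior)
  for (i in 1:20) {
    oracle <- ebgm_integration_oracle(a[i], E[i], prior)
    expect_lt(abs(st$ebgm[i] / oracle - 1), 0.01)
  }
  # quantile below geometric mean, always
  expect_true(all(st$ebgm05 < st$ebgm))
})

test_that("shrinkage never overshoots the observed ratio", {
  prior <- make_prior(2, 2, 1, 0.2, 0.9)
  a <- c(1, 3, 10, 50, 200); E <- c(0.5, 2, 5, 20, 40)
  st <- mgps_stats(a, E, prior)
  prior_mean_log <- log(0.9 * 2 / 2 + 0.1 * 1 / 0.2)
  for (i in seq_along(a)) {
    # posterior geometric mean lies between prior mass and observed a/E
    expect_lte(abs(log(st$ebgm[i])), abs(log(a[i] / E[i])) + 0.02 +
                 abs(prior_mean_log))
  }
  # no-signal case: a = E under a prior concentrated at 1
  conc <- make_prior(2000, 2000, 2000, 2000, 0.5)
  st1 <- mgps_stats(30, 30, conc)
  expect_lt(abs(st1$ebgm - 1), 0.05)
  # diffuse prior, strong signal: shrinkage pulls slightly toward 1
  dif <- make_prior(0.2, 0.02, 0.2, 0.02, 0.5)
  st10 <- mgps_stats(500, 50, dif)
  expect_gt(st10$ebgm, 8)
  expect_lt(st10$ebgm, 10.5)
})

test_that("flags follow the four-criteria rule", {
  # strong cell passes all four under a near-flat prior
  prior <- make_prior(0.5, 0.5, 0.5, 0.5, 0.5)
  cells <- data.table::data.table(
    event = c("strong", "tiny", "null"),
    a = c(20L, 2L, 30L), b = c(80L, 8L, 2970L),
    c = c(100L, 100L, 97L), d = c(9800L, 9890L, 6903L))
  cells[, `:=`(N = a + b + c + d)]
  cells[, E := (a + b) * (a + c) / N]
  st <- signal_table(cells, prior = prior)
  strong <- st[event == "strong"]
  expect_true(strong$flag_ror && strong$flag_prr && strong$flag_bcpnn &&
                strong$flag_mgps && strong$flag_positive)
  # a = 2: minimum-count rule blocks ROR and PRR regardless of magnitude
  tiny <- st[event == "tiny"]
  expect_false(tiny$flag_ror || tiny$flag_prr || tiny$flag_positive)
  # independence: not a positive signal
  expect_false(st[event == "null"]$flag_positive)
})

test_that("ranking is stable, descending, label-tie-broken", {
  res <- data.table::data.table(
    event = c("c", "a", "b"), n = c(5L, 9L, 9L),
    ror = c(2, 3, 1), ebgm = c(1, 2, 3),
    flag_positive = c(TRUE, TRUE, FALSE))
  r <- rank_signals(res, by = "n")
  expect_identical(r$event, c("a", "b", "c"))
  expect_identical(nrow(rank_signals(res[0], by = "n")), 0L)
  expect_error(rank_signals(res, by = "bogus"))
  expect_identical(rank_signals(res, by = "ror", positive_only = TRUE)$event,
                   c("a", "c"))
})

test_that("ROR and PRR agree for rare events", {
  # rare-event approximation: a << a+b and c << c+d
  set.seed(9)
  for (i in 1:25) {
    ab <- 5000; cd <- 100000
    a <- rbinom(1, ab, 0.005) + 1; c_ <- rbinom(1, cd, 0.004) + 1
    ror <- ror_stats(a, ab - a, c_, cd - c_)$ror
    prr <- prr_stats(a, ab - a, c_, cd - c_)$prr
    expect_lt(abs(ror / prr - 1), 0.05)
  }
})
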