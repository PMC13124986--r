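demo_row <- function(pid, case, fda) {
  data.table::data.table(primaryid = pid, caseid = case, fda_dt = fda)
}

test_that("deduplication keeps the latest FDA date, then highest primary id", {
  # later FDA date wins
  x <- demo_row(c(1, 2), c(100, 100), c(20140101L, 20150101L))
  expect_identical(deduplicate(x)$primaryid, 2)
  # FDA date tie: highest primary id wins
  y <- demo_row(c(7, 9), c(100, 100), c(20140101L, 20140101L))
  expect_identical(deduplicate(y)$primaryid, 9)
  # a dated version beats an undated one
  z <- demo_row(c(5, 3), c(100, 100), c(NA_integer_, 20140101L))
  expect_identical(deduplicate(z)$primaryid, 3)
  # all distinct cases: identity (up to sort order)
  w <- demo_row(c(3, 1, 2), c(30, 10, 20), rep(20200101L, 3))
  expect_identical(deduplicate(w)$primaryid, c(1, 2, 3))
})

test_that("deduplication is idempotent, never invents rows, matches ground truth", {
  sh <- shared_sim()
  demo <- sh$sim$tables$demo
  d1 <- deduplicate(demo)
  expect_identical(deduplicate(d1), d1)
  expect_true(all(d1$primaryid %in% demo$primaryid))
  expect_identical(anyDuplicated(d1$caseid), 0L)
  truth <- sh$sim$truth$canonical_version
  expect_identical(sort(d1$primaryid),
                   sort(as.numeric(truth$primaryid)))
})

test_that("target selection normalizes names and honors role codes", {
  drug <- data.table::data.table(
    primaryid = 1:5,
    drugname = c("VORTIOXETINE HBR", "Vortioxetine", "vortioxetine  ",
                 "Brintellix plus", "BRINTELLIX"),
    role_cod = c("PS", "C", "PS", "PS", "SS"))
  syn <- pv_vortioxetine_synonyms()
  # exact-after-normalization: combination string not captured; role C
  # excluded under the default PS filter
  expect_identical(select_target_reports(drug, syn), c(1L, 3L))
  expect_identical(select_target_reports(drug, syn, roles = c("PS", "SS")),
                   c(1L, 3L, 5L))
  expect_error(select_target_reports(drug, character(0)), "non-empty")
})

test_that("malformed dates are logged, rows retained", {
  sim <- simulate_reports(sim_config(n_reports = 30, seed = 9,
                                     duplicate_rate = 0))
  d <- sim_to_dir(sim)
  f <- list.files(d, pattern = "^DEMO", full.names = TRUE)[1]
  lines <- readLines(f)
  parts <- strsplit(lines[2], "$", fixed = TRUE)[[1]]
  parts[4] <- "2024133X"  # corrupt fda_dt
  lines[2] <- paste(parts, collapse = "$")
  writeLines(lines, f)
  expect_warning(tabs <- read_faers_ascii(d), "malformed date")
  expect_identical(nrow(tabs$demo), nrow(sim$tables$demo))
  expect_true(is.na(tabs$demo$fda_dt[tabs$demo$primaryid ==
                                       as.numeric(parts[1])]))
})

test_that("missing table files are reported by name", {
  expect_error(read_faers_ascii(withr::local_tempdir()), "DEMO")
  sim <- simulate_reports(sim_config(n_reports = 10, seed = 3,
                                     quarters = "2024Q1"))
  d <- sim_to_dir(sim)
  file.remove(file.path(d, "REAC24Q1.txt"))
  expect_error(read_faers_ascii(d), "REAC24Q1.txt")
})

test_that("age and weight units are normalized during assembly", {
  sim <- simulate_reports(sim_config(n_reports = 6, seed = 11,
                                     duplicate_rate = 0,
                                     quarters = "2024Q1"))
  demo <- sim$tables$demo
  demo$age <- c(6, 60, 600, 18, 154, NA)
  demo$age_cod <- c("DEC", "YR", "MON", "YR", "YR", NA)
  demo$sex <- c("F", "M", "F", "UNK", "F", "M")
  demo$wt <- c(154, 70, NA, 80, 200, 90)
  demo$wt_cod <- c("LBS", "KG", NA, "KG", "KG", "KG")
  sim$tables$demo <- demo
  d <- sim_to_dir(sim)
  tabs <- read_faers_ascii(d)
  target <- select_target_reports(tabs$drug, pv_vortioxetine_synonyms())
  rec <- NULL
  expect_warning(rec <- assemble_records(tabs, tabs$demo$primaryid),
                 "implausible age")
  r <- rec$reports[order(primaryid)]
  expect_equal(r$age_years, c(60, 60, 50, 18, NA, NA))  # 154 yr implausible
  expect_equal(r$weight_kg[1], 69.85, tolerance = 1e-3)  # 154 lb
  expect_identical(r$sex[4], NA_character_)  # UNK -> missing
})

test_that("assembled cohort matches the generator exactly", {
  sh <- shared_sim()
  d <- sim_to_dir(sh$sim)
  tabs <- read_faers_ascii(d)
  demo <- deduplicate(tabs$demo)
  target <- select_target_reports(tabs$drug, pv_vortioxetine_synonyms())
  rec <- assemble_records(tabs, target, dedup_demo = demo)
  truth <- sh$sim$truth$reports
  expect_identical(sort(rec$reports$primaryid),
                   sort(as.numeric(truth[truth$is_target == TRUE,
                                         primaryid])))
  # join conservation: every retained reaction's report survived dedup
  expect_true(all(rec$background_reactions$primaryid %in% demo$primaryid))
  # unique (report, PT) counting
  expect_identical(anyDuplicated(rec$reactions), 0L)
})
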