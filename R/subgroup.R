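# Descriptive cohort characterization and r x 2 contingency testing of
# suicide-related reporting against demographic factors.

#' Label reports carrying a suicide-related preferred term
#'
#' A report is suicide-related iff at least one of its PTs matches the
#' supplied list (case-insensitive exact match after whitespace
#' normalization).
#'
#' @param reactions report-PT pairs (`primaryid`, `pt`).
#' @param suicide_pts non-empty character vector of PTs.
#' @param ids report ids to label; default the ids present in
#'   `reactions`.
#' @return `data.table` with columns `primaryid`, `suicide` (logical).
#' @export
label_suicide_reports <- function(reactions, suicide_pts, ids = NULL) {
  if (length(suicide_pts) == 0) stop("suicide PT list must be non-empty")
  reac <- as.data.table(reactions)
  if (is.null(ids)) ids <- sort(unique(reac$primaryid))
  hits <- unique(reac[normalize_term(pt) %chin%
                        normalize_term(suicide_pts), primaryid])
  data.table(primaryid = ids, suicide = ids %in% hits)
}

#' Re-bin ages under alternative schemes
#'
#' * `"table6"`: `<18`, `18-64`, `65-85`, `>85` (65-85 inclusive of both
#'   bounds).
#' * `"fda_warning"`: `<=24`, `25-64`, `>=65` — the binning of the FDA
#'   boxed-warning age strata; the boundary age 24.0 falls in `<=24`.
#'
#' @param age_years numeric ages in years (missing allowed).
#' @param scheme `"table6"` (default) or `"fda_warning"`.
#' @return character vector of bin labels (`NA` for missing ages).
#' @export
age_rebin <- function(age_years, scheme = c("table6", "fda_warning")) {
  scheme <- match.arg(scheme)
  if (scheme == "table6") {
    ifelse(is.na(age_years), NA_character_,
           ifelse(age_years < 18, "<18",
                  ifelse(age_years < 65, "18-64",
                         ifelse(age_years <= 85, "65-85", ">85"))))
  } else {
    ifelse(is.na(age_years), NA_character_,
           ifelse(age_years <= 24, "<=24",
                  ifelse(age_years < 65, "25-64", ">=65")))
  }
}

.weight_bins <- function(wt) {
  ifelse(is.na(wt), NA_character_,
         ifelse(wt < 50, "<50",
                ifelse(wt <= 100, "50-100", ">100")))
}

#' Descriptive characterization of a cohort
#'
#' Counts and percentages of the cohort total (2 decimal places) per
#' category for the requested groupings; missing values are reported as
#' their own `"Missing"` row, so category counts sum to the cohort size.
#'
#' @param reports cohort report table (from [assemble_records()], element
#'   `reports`).
#' @param keys groupings to tabulate, any of `"sex"`, `"age"`, `"weight"`,
#'   `"country"`, `"reporter"`, `"outcome"`, `"year"`.
#' @param top_k for `"country"`, keep the `top_k` most frequent countries
#'   and pool the rest as `"Other"` (default 5).
#' @return `data.table` with columns `characteristic`, `category`, `n`,
#'   `pct`.
#' @export
characterize_cohort <- function(reports,
                                keys = c("sex", "age", "weight", "country",
                                         "reporter", "outcome", "year"),
                                top_k = 5) {
  known <- c("sex", "age", "weight", "country", "reporter", "outcome",
             "year")
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown grouping key(s): ",
                        paste(bad, collapse = ", "))
  reports <- as.data.table(reports)
  total <- nrow(reports)
  one <- function(characteristic, values, order_by_n = FALSE) {
    values <- ifelse(is.na(values), "Missing", as.character(values))
    tab <- data.table(category = values)[, .(n = .N), by = category]
    if (order_by_n) setorder(tab, -n, category) else setorder(tab, category)
    tab[, `:=`(characteristic = characteristic,
               pct = if (total > 0) round(100 * n / total, 2) else
                 NA_real_)]
    tab[, .(characteristic, category, n, pct)]
  }
  pieces <- list()
  for (k in keys) {
    pieces[[k]] <- switch(k,
      sex = one("sex", reports$sex),
      age = one("age_years", age_rebin(reports$age_years)),
      weight = one("weight_kg", .weight_bins(reports$weight_kg)),
      country = {
        x <- reports$country
        topc <- names(sort(table(x), decreasing = TRUE))
        topc <- topc[seq_len(min(top_k, length(topc)))]
        x <- ifelse(is.na(x), NA_character_,
                    ifelse(x %in% topc, x, "Other"))
        one("country", x, order_by_n = TRUE)
      },
      reporter = one("reporter", reports$reporter),
      outcome = {
        oc <- unlist(strsplit(reports$outcomes[!is.na(reports$outcomes)],
                              ";", fixed = TRUE))
        tab <- data.table(category = oc)[, .(n = .N), by = category]
        setorder(tab, category)
        tab[, `:=`(characteristic = "outcome",
                   pct = if (total > 0) round(100 * n / total, 2) else
                     NA_real_)]
        tab[, .(characteristic, category, n, pct)]
      },
      year = one("reporting_year", format(reports$fda_date, "%Y")))
  }
  rbindlist(pieces)
}

#' r x 2 contingency test of a factor against suicide-related reporting
#'
#' Pearson chi-square without continuity correction by default. Under
#' `policy = "auto"` the test switches to Fisher's exact test when any
#' expected cell count is below 5 (2 x 2 via the hypergeometric
#' distribution, r x 2 via network enumeration). All-zero category rows
#' are dropped with a warning and the degrees of freedom adjusted.
#' Missing-category rows are the caller's responsibility to exclude
#' (descriptive output keeps them; tests do not).
#'
#' @param counts r x 2 matrix, rows = factor categories (named), columns
#'   = (non-suicide, suicide) counts.
#' @param policy `"auto"` (default), `"pearson"` or `"fisher"`.
#' @param correction Yates continuity correction for the Pearson branch
#'   (default `FALSE`).
#' @param factor_name label carried into the result.
#' @return object of class `subgroup_test`: `factor_name`, `counts`,
#'   `statistic` (chi-square, `NA` for Fisher), `df`, `p_value`,
#'   `test_used`, `expected`.
#' @export
subgroup_test <- function(counts, policy = c("auto", "pearson", "fisher"),
                          correction = FALSE, factor_name = NULL) {
  policy <- match.arg(policy)
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 || nrow(counts) < 2) {
    stop("counts must be an r x 2 matrix with r >= 2")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  zero_rows <- rowSums(counts) == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows),
            " all-zero category row(s) dropped; df adjusted")
    counts <- counts[!zero_rows, , drop = FALSE]
    if (nrow(counts) < 2) stop("fewer than 2 non-empty categories remain")
  }
  if (any(colSums(counts) == 0)) stop("a column of counts is all zero")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  use_fisher <- switch(policy,
                       pearson = FALSE,
                       fisher = TRUE,
                       auto = any(expected < 5))
  if (use_fisher) {
    ft <- fisher.test(counts, workspace = 2e6)
    res <- list(statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value, test_used = "fisher")
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = correction))
    res <- list(statistic = unname(ct$statistic),
                df = unname(ct$parameter),
                p_value = ct$p.value, test_used = "pearson")
  }
  structure(c(list(factor_name = factor_name, counts = counts,
                   expected = expected), res),
            class = "subgroup_test")
}

#' @export
print.subgroup_test <- function(x, ...) {
  cat("Subgroup contingency test",
      if (!is.null(x$factor_name)) paste0(" (", x$factor_name, ")"),
      ": ", x$test_used, "\n", sep = "")
  if (x$test_used == "pearson") {
    cat(sprintf("  chi-square = %.2f, df = %d, p = %.3g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("  p = %.3g (exact)\n", x$p_value))
  }
  invisible(x)
}

#' Cross-tabulate a demographic factor against the suicide label
#'
#' Builds the r x 2 (non-suicide, suicide) count matrix for one factor of
#' an assembled cohort, excluding reports with the factor missing, and
#' runs [subgroup_test()].
#'
#' @param reports cohort report table.
#' @param labels `data.table` from [label_suicide_reports()].
#' @param factor one of `"sex"`, `"age"`, `"weight"`.
#' @param policy,correction passed to [subgroup_test()].
#' @return a `subgroup_test` object.
#' @export
subgroup_factor_test <- function(reports, labels,
                                 factor = c("sex", "age", "weight"),
                                 policy = "auto", correction = FALSE) {
  factor <- match.arg(factor)
  reports <- as.data.table(reports)
  x <- merge(reports, labels, by = "primaryid")
  cat_vals <- switch(factor,
                     sex = x$sex,
                     age = age_rebin(x$age_years),
                     weight = .weight_bins(x$weight_kg))
  keep <- !is.na(cat_vals)
  tab <- table(category = cat_vals[keep],
               suicide = factor(x$suicide[keep], levels = c(FALSE, TRUE)))
  counts <- matrix(as.integer(tab), ncol = 2,
                   dimnames = list(rownames(tab),
                                   c("non_suicide", "suicide")))
  subgroup_test(counts, policy = policy, correction = correction,
                factor_name = factor)
}
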