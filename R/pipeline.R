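# End-to-end pipeline: ingest -> dedup -> primary-suspect screen ->
# contingency cells -> four disproportionality algorithms -> combined
# flags -> time-to-onset -> subgroup tests, with rendered tables and a
# run manifest. Re-running with the same inputs and configuration is
# bit-identical (nothing downstream of the generator is stochastic unless
# the bootstrap CI is requested).

#' Pipeline configuration
#'
#' @param input_dir directory of FAERS-dialect quarterly ASCII files.
#' @param quarters optional quarter subset (`"2013Q4"` style).
#' @param synonyms drug synonym list: a character vector or the path of a
#'   one-name-per-line text file.
#' @param pt_soc PT-to-SOC map: a data.frame (`pt`, `soc`) or the path of
#'   a 2-column TSV. MedDRA is licensed, so the user supplies this.
#' @param suicide_pts suicide-related PT list: character vector or file
#'   path.
#' @param thresholds [signal_thresholds()] list.
#' @param zero_policy `"undefined"` or `"haldane"` (see [ror_stats()]).
#' @param chisq_correction Yates correction switch for the PRR chi-square
#'   and the subgroup Pearson tests (default off).
#' @param tto_filter optional PT filter for the time-to-onset fit
#'   (default all events).
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   rendered tables and the manifest there.
#' @param seed seed for any stochastic option (bootstrap CIs).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, quarters = NULL, synonyms,
                            pt_soc, suicide_pts = pv_suicide_pts(),
                            thresholds = signal_thresholds(),
                            zero_policy = "undefined",
                            chisq_correction = FALSE,
                            tto_filter = NULL, output_dir = NULL,
                            seed = 1L) {
  if (missing(pt_soc) || is.null(pt_soc)) {
    stop("pipeline_config: 'pt_soc' is required (path to a 2-column ",
         "PT->SOC TSV or a data.frame); MedDRA cannot be bundled")
  }
  if (is.character(pt_soc) && length(pt_soc) == 1) {
    if (!file.exists(pt_soc)) {
      stop("pipeline_config: 'pt_soc' file not found: ", pt_soc)
    }
    pt_soc <- read_pt_soc_map(pt_soc)
  }
  if (is.character(synonyms) && length(synonyms) == 1 &&
      file.exists(synonyms)) {
    synonyms <- read_term_list(synonyms)
  }
  if (length(synonyms) == 0) stop("pipeline_config: empty synonym list")
  if (is.character(suicide_pts) && length(suicide_pts) == 1 &&
      file.exists(suicide_pts)) {
    suicide_pts <- read_term_list(suicide_pts)
  }
  structure(list(input_dir = input_dir, quarters = quarters,
                 synonyms = synonyms, pt_soc = as.data.table(pt_soc),
                 suicide_pts = suicide_pts, thresholds = thresholds,
                 zero_policy = zero_policy,
                 chisq_correction = chisq_correction,
                 tto_filter = tto_filter, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full signal-detection pipeline
#'
#' @param config a [pipeline_config()].
#' @return list bundle: `cohort` (assembled records), `signals_pt`,
#'   `signals_soc` (signal tables), `tto` (`weibull_fit`),
#'   `cumulative_incidence`, `subgroups` (sex/age/weight
#'   `subgroup_test`s), `characteristics`, `suicide_characteristics`,
#'   `labels`, `manifest` (stage counts, config echo, package version).
#'   When `config$output_dir` is set the bundle is also rendered to disk
#'   via [render_tables()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tables <- .stage("ingest",
                   read_faers_ascii(config$input_dir, config$quarters))
  demo <- .stage("dedup", deduplicate(tables$demo))
  target <- .stage("select",
                   select_target_reports(tables$drug, config$synonyms))
  cohort <- .stage("assemble",
                   assemble_records(tables, target, dedup_demo = demo))

  cells_pt <- .stage("cells", build_cells(
    cohort$background_reactions, cohort$reports$primaryid,
    cohort$background_ids, level = "PT"))
  cells_soc <- .stage("cells", build_cells(
    cohort$background_reactions, cohort$reports$primaryid,
    cohort$background_ids, level = "SOC", pt_soc = config$pt_soc))
  signals_pt <- .stage("signals", signal_table(
    cells_pt, thresholds = config$thresholds,
    zero_policy = config$zero_policy,
    correction = config$chisq_correction))
  signals_soc <- .stage("signals", signal_table(
    cells_soc, thresholds = config$thresholds,
    zero_policy = config$zero_policy,
    correction = config$chisq_correction))

  onsets <- .stage("tto", extract_onsets(cohort, config$synonyms,
                                         event_filter = config$tto_filter))
  tto <- if (length(onsets$onset_days) >= 10 &&
               length(unique(onsets$onset_days)) >= 2) {
    .stage("tto", fit_weibull(onsets, seed = config$seed))
  } else NULL
  cuminc <- if (length(onsets$onset_days))
    cumulative_incidence(onsets) else NULL

  labels <- .stage("subgroups", label_suicide_reports(
    cohort$reactions, config$suicide_pts, ids = cohort$reports$primaryid))
  subgroups <- lapply(c(sex = "sex", age = "age", weight = "weight"),
                      function(f) {
    tryCatch(subgroup_factor_test(cohort$reports, labels, f,
                                  correction = config$chisq_correction),
             error = function(e) NULL)
  })
  chars <- .stage("subgroups", characterize_cohort(cohort$reports))
  suicide_ids <- labels[suicide == TRUE, primaryid]
  suicide_chars <- if (length(suicide_ids)) {
    characterize_cohort(cohort$reports[primaryid %in% suicide_ids])
  } else NULL

  manifest <- list(
    package_version = as.character(packageVersion("pvsignal")),
    seed = config$seed,
    quarters = sort(unique(tables$demo$quarter)),
    counts = list(
      demo_rows_read = nrow(tables$demo),
      reports_after_dedup = nrow(demo),
      duplicates_removed = nrow(tables$demo) - nrow(demo),
      target_reports = nrow(cohort$reports),
      cohort_reactions = nrow(cohort$reactions),
      suicide_reports = length(suicide_ids),
      tto_n = length(onsets$onset_days),
      tto_excluded = onsets$n_excluded,
      pt_events = nrow(signals_pt),
      soc_events = nrow(signals_soc),
      positive_pt_signals = sum(signals_pt$flag_positive),
      positive_soc_signals = sum(signals_soc$flag_positive)),
    config = list(synonyms = config$synonyms,
                  suicide_pts = config$suicide_pts,
                  thresholds = config$thresholds,
                  zero_policy = config$zero_policy,
                  chisq_correction = config$chisq_correction,
                  tto_filter = config$tto_filter),
    ingest_log = attr(tables, "ingest_log"))

  bundle <- list(cohort = cohort, signals_pt = signals_pt,
                 signals_soc = signals_soc, tto = tto,
                 cumulative_incidence = cuminc, subgroups = subgroups,
                 characteristics = chars,
                 suicide_characteristics = suicide_chars,
                 labels = labels, manifest = manifest)
  if (!is.null(config$output_dir)) {
    render_tables(bundle, config$output_dir)
  }
  bundle
}

.render_signals <- function(signals, path) {
  cols <- c("event", "n", "ror", "ror_lo95", "ror_hi95", "prr",
            "prr_chisq", "ebgm", "ebgm05", "ic", "ic025")
  out <- as.data.table(signals)[, cols, with = FALSE]
  num <- setdiff(cols, c("event", "n"))
  out[, (num) := lapply(.SD, function(x) round(x, 2)), .SDcols = num]
  out[, flags := apply(as.data.table(signals)[
    , .(flag_ror, flag_prr, flag_bcpnn, flag_mgps, flag_positive)], 1,
    function(f) paste(substr(c("ror", "prr", "bcpnn", "mgps", "positive")[
      as.logical(f)], 1, 8), collapse = ","))]
  setnames(out, c("event", "n", "ROR", "ROR_lo", "ROR_hi", "PRR",
                  "chisq", "EBGM", "EBGM05", "IC", "IC025", "flags"))
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
}

#' Render a pipeline result bundle to disk
#'
#' Writes TSV tables (fixed column order, 2-decimal rounding) mirroring
#' the standard signal/onset/subgroup report layouts, plus a
#' machine-readable JSON (`results.json`, full precision) and the run
#' manifest (`manifest.json`).
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
render_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  for (lev in c("pt", "soc")) {
    path <- file.path(dir, paste0("signals_", lev, ".tsv"))
    .render_signals(bundle[[paste0("signals_", lev)]], path)
    files <- c(files, path)
  }
  if (!is.null(bundle$tto)) {
    t <- bundle$tto
    tto_tab <- data.table(
      n = t$n,
      median_days = round(t$median_days, 1),
      q25 = round(t$q25, 1), q75 = round(t$q75, 1),
      shape = round(t$shape, 2),
      shape_lo95 = round(t$shape_lo95, 2),
      shape_hi95 = round(t$shape_hi95, 2),
      scale_days = round(t$scale, 1),
      classification = t$classification)
    path <- file.path(dir, "tto_weibull.tsv")
    fwrite(tto_tab, path, sep = "\t", quote = FALSE)
    files <- c(files, path)
  }
  if (!is.null(bundle$cumulative_incidence)) {
    path <- file.path(dir, "cumulative_incidence.tsv")
    fwrite(bundle$cumulative_incidence[
      , .(day, cum_incidence = round(cum_incidence, 4))],
      path, sep = "\t", quote = FALSE)
    files <- c(files, path)
  }
  for (nm in c("characteristics", "suicide_characteristics")) {
    if (is.null(bundle[[nm]])) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    fwrite(bundle[[nm]], path, sep = "\t", quote = FALSE)
    files <- c(files, path)
  }
  sg <- bundle$subgroups[!vapply(bundle$subgroups, is.null, logical(1))]
  if (length(sg)) {
    sg_tab <- rbindlist(lapply(sg, function(s) data.table(
      factor = s$factor_name, test = s$test_used,
      chisq = round(s$statistic, 2), df = s$df,
      p_value = round(s$p_value, 4))))
    path <- file.path(dir, "subgroup_tests.tsv")
    fwrite(sg_tab, path, sep = "\t", quote = FALSE)
    files <- c(files, path)
  }
  res_json <- list(
    signals_pt = as.data.frame(bundle$signals_pt),
    signals_soc = as.data.frame(bundle$signals_soc),
    tto = if (!is.null(bundle$tto)) unclass(bundle$tto) else NULL,
    subgroups = lapply(sg, function(s) list(
      factor = s$factor_name, test = s$test_used, chisq = s$statistic,
      df = s$df, p_value = s$p_value,
      counts = as.data.frame(as.table(s$counts)))))
  path <- file.path(dir, "results.json")
  jsonlite::write_json(res_json, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, path)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  files <- c(files, path)
  invisible(files)
}
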