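# Synthetic FAERS-like report generator with known ground truth. It emulates
# the ingredients the downstream stages consume: a population of spontaneous
# reports with demographic missingness typical of the database, a drug x PT
# event matrix with planted relative reporting rates, injected duplicate
# case versions (same Case ID, later FDA dates, higher Primary IDs),
# therapy-start / event dates with Weibull-distributed onset lags, and
# outcome codes.

#' Configuration for the synthetic report generator
#'
#' The defaults emulate the shape of a real antidepressant cohort in a
#' spontaneous-reporting database: demographic missingness follows the
#' pattern typical of consumer-dominated reporting (about half of ages and
#' four-fifths of weights absent), onset lags follow an early-failure
#' Weibull (shape 0.58, scale 60 days, giving a median near the observed
#' two-to-three-week onset), and each report carries on average
#' `events_per_report` preferred terms.
#'
#' @param n_reports number of distinct cases to simulate.
#' @param n_drugs number of distinct drugs; drug 1 is the target drug and is
#'   named by `target_drug`, the rest `DRUG_002`, ...
#' @param n_events number of distinct preferred terms. Up to 30, names come
#'   from the bundled synthetic PT dictionary (so the seven suicide-related
#'   PTs are present); beyond 30, synthetic `PT_0031` style names are
#'   appended and mapped round-robin onto the five synthetic SOCs.
#' @param baseline_event_probs probability vector over events, must sum
#'   to 1 (within 1e-9). Default decreasing weights `1/(rank+4)`,
#'   normalized, mimicking the long-tailed PT frequency distribution.
#' @param events_per_report mean number of PT mentions per report at
#'   relative rate 1.
#' @param planted_rr data.frame with columns `drug`, `event`, `rr`: relative
#'   reporting rate of `event` for reports whose suspect is `drug`
#'   (unlisted pairs default to 1). Event e occurs in a report with suspect
#'   drug g independently with probability
#'   `baseline_event_probs[e] * events_per_report * rr(g, e)` (capped at 1,
#'   with a warning when the cap binds).
#' @param duplicate_rate fraction of cases emitted as 2-3 versions with
#'   strictly increasing FDA dates (demographics held fixed across
#'   versions, so only the dedup rule distinguishes them).
#' @param onset_shape,onset_scale_days Weibull shape and scale of the
#'   therapy-start-to-event lag in days.
#' @param p_event_date_missing,p_ther_missing fractions of reports lacking
#'   an event date / a therapy-start date.
#' @param demographic_spec named list overriding any of the marginal
#'   distributions; see `pv_default_demographics()` for the structure.
#' @param quarters character vector of quarters (`"2024Q1"` style) across
#'   which FDA receipt dates are spread uniformly.
#' @param target_drug name given to drug 1.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_reports = 10000,
                       n_drugs = 20,
                       n_events = 30,
                       baseline_event_probs = NULL,
                       events_per_report = 3,
                       planted_rr = NULL,
                       duplicate_rate = 0.1,
                       onset_shape = 0.58,
                       onset_scale_days = 60,
                       p_event_date_missing = 0.3,
                       p_ther_missing = 0.1,
                       demographic_spec = NULL,
                       quarters = c("2024Q1", "2024Q2", "2024Q3", "2024Q4"),
                       target_drug = "Vortioxetine",
                       seed = 1L) {
  stopifnot(n_reports >= 0, n_drugs >= 1, n_events >= 1,
            events_per_report > 0,
            duplicate_rate >= 0, duplicate_rate <= 1,
            onset_shape > 0, onset_scale_days > 0,
            p_event_date_missing >= 0, p_event_date_missing <= 1,
            p_ther_missing >= 0, p_ther_missing <= 1)
  if (is.null(baseline_event_probs)) {
    w <- 1 / (seq_len(n_events) + 4)
    baseline_event_probs <- w / sum(w)
  }
  if (length(baseline_event_probs) != n_events ||
      any(baseline_event_probs < 0) ||
      abs(sum(baseline_event_probs) - 1) > 1e-9) {
    stop("baseline_event_probs must be a length-", n_events,
         " non-negative vector summing to 1 (within 1e-9)")
  }
  if (!is.null(planted_rr)) {
    planted_rr <- as.data.frame(planted_rr)
    stopifnot(all(c("drug", "event", "rr") %in% names(planted_rr)),
              all(planted_rr$rr >= 0),
              all(planted_rr$drug >= 1), all(planted_rr$drug <= n_drugs),
              all(planted_rr$event >= 1), all(planted_rr$event <= n_events))
  }
  demo_spec <- pv_default_demographics()
  if (!is.null(demographic_spec)) {
    stopifnot(all(names(demographic_spec) %in% names(demo_spec)))
    demo_spec[names(demographic_spec)] <- demographic_spec
  }
  structure(list(
    n_reports = as.integer(n_reports), n_drugs = as.integer(n_drugs),
    n_events = as.integer(n_events),
    baseline_event_probs = baseline_event_probs,
    events_per_report = events_per_report,
    planted_rr = planted_rr, duplicate_rate = duplicate_rate,
    onset_shape = onset_shape, onset_scale_days = onset_scale_days,
    p_event_date_missing = p_event_date_missing,
    p_ther_missing = p_ther_missing,
    demographic_spec = demo_spec, quarters = quarters,
    target_drug = target_drug, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default demographic marginals for the synthetic generator
#'
#' Sex, age, weight, country, reporter-occupation and outcome marginals
#' with the missingness proportions characteristic of a consumer-dominated
#' antidepressant cohort (about 13% of sexes, 50% of ages and 80% of
#' weights unreported).
#'
#' @return named list of marginal specifications.
#' @export
pv_default_demographics <- function() {
  list(
    sex = c(F = 0.608, M = 0.266, missing = 0.126),
    age_mean = 45, age_sd = 18, age_missing = 0.497,
    weight_mean = 75, weight_sd = 15, weight_missing = 0.80,
    countries = c(US = 0.770, JP = 0.043, FR = 0.029, CA = 0.020,
                  GB = 0.015, DE = 0.123),
    reporters = c(CN = 0.499, MD = 0.261, OT = 0.070, PH = 0.026,
                  missing = 0.144),
    outcomes = c(OT = 0.8254, HO = 0.1117, DE = 0.0310, LT = 0.0159,
                 DS = 0.0148, CA = 0.0012)
  )
}

.sample_cat <- function(n, probs) {
  labs <- names(probs)
  x <- labs[sample.int(length(probs), n, replace = TRUE, prob = probs)]
  x[x == "missing"] <- NA_character_
  x
}

.event_names <- function(n_events) {
  dict <- pv_example_pt_soc()
  if (n_events <= nrow(dict)) return(dict$pt[seq_len(n_events)])
  extra <- sprintf("PT_%04d", seq(nrow(dict) + 1L, n_events))
  c(dict$pt, extra)
}

#' SOC map covering the generator's event names
#'
#' Extends the bundled synthetic dictionary with round-robin SOC
#' assignments for generated `PT_xxxx` names when `n_events > 30`.
#'
#' @param n_events number of events in the simulated configuration.
#' @return `data.table` with columns `pt`, `soc`.
#' @export
sim_pt_soc_map <- function(n_events) {
  dict <- pv_example_pt_soc()
  pts <- .event_names(n_events)
  if (n_events <= nrow(dict)) return(dict[seq_len(n_events)])
  socs <- unique(dict$soc)
  extra <- data.table(
    pt = pts[seq(nrow(dict) + 1L, n_events)],
    soc = socs[((seq(nrow(dict) + 1L, n_events) - 1L) %% length(socs)) + 1L])
  rbind(dict, extra)
}

#' Simulate a FAERS-shaped quarterly table set with ground truth
#'
#' Each case gets one suspect drug (uniform over drugs), demographic
#' fields, an FDA receipt date uniform over the configured quarters, and an
#' independent Bernoulli draw per preferred term with probability
#' proportional to the baseline event probability scaled by the planted
#' relative reporting rate of its suspect drug. A `duplicate_rate` fraction
#' of cases is emitted in 2-3 versions with strictly increasing FDA dates
#' and Primary IDs; demographics are identical across versions. Therapy
#' start and event dates embed a Weibull onset lag (rounded to whole days,
#' minimum 0).
#'
#' @param config a [sim_config()].
#' @return list with `tables` (the five FAERS-dialect tables, each carrying
#'   a `quarter` column) and `truth`, a list with elements
#'   `planted_rr`, `onset_shape`, `onset_scale_days`,
#'   `duplicate_map` (caseid -> all primaryids emitted),
#'   `canonical_version` (caseid -> the primaryid dedup must keep),
#'   `reports` (per-case truth: suspect drug, onset lag, date availability)
#'   and `event_names`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  spec <- config$demographic_spec
  ev_names <- .event_names(config$n_events)
  drug_names <- c(config$target_drug,
                  sprintf("DRUG_%03d", seq_len(config$n_drugs))[-1])

  caseid <- 10000000L + seq_len(n)
  drug_idx <- if (n) sample.int(config$n_drugs, n, replace = TRUE) else integer(0)

  # event probability matrix rows = drug, cols = event
  p_base <- config$baseline_event_probs * config$events_per_report
  pmat <- matrix(rep(p_base, each = config$n_drugs),
                 nrow = config$n_drugs)
  if (!is.null(config$planted_rr)) {
    for (i in seq_len(nrow(config$planted_rr))) {
      r <- config$planted_rr[i, ]
      pmat[r$drug, r$event] <- pmat[r$drug, r$event] * r$rr
    }
  }
  if (any(pmat > 1)) {
    warning("some drug-event occurrence probabilities capped at 1; ",
            "empirical relative rates for those pairs will fall short ",
            "of the planted values")
    pmat <- pmin(pmat, 1)
  }

  # per-report event sets, vectorized within suspect-drug groups
  reac_case <- vector("list", config$n_drugs)
  reac_pt <- vector("list", config$n_drugs)
  for (g in seq_len(config$n_drugs)) {
    idx <- which(drug_idx == g)
    if (!length(idx)) next
    hits <- matrix(runif(length(idx) * config$n_events),
                   nrow = length(idx)) <
      matrix(rep(pmat[g, ], each = length(idx)), nrow = length(idx))
    w <- which(hits, arr.ind = TRUE)
    reac_case[[g]] <- caseid[idx][w[, 1]]
    reac_pt[[g]] <- w[, 2]
  }
  reac0 <- data.table(
    caseid = as.integer(unlist(c(list(integer(0)), reac_case))),
    event = as.integer(unlist(c(list(integer(0)), reac_pt))))
  setorder(reac0, caseid, event)

  # demographics (one draw per case; constant across duplicate versions)
  sex <- .sample_cat(n, spec$sex)
  age_years <- pmin(pmax(round(rnorm(n, spec$age_mean, spec$age_sd)), 1), 95)
  age_missing <- runif(n) < spec$age_missing
  # a slice of ages is coded in non-year units to exercise conversion
  age_cod <- sample(c("YR", "DEC", "MON"), n, replace = TRUE,
                    prob = c(0.9, 0.05, 0.05))
  age_val <- ifelse(age_cod == "YR", age_years,
                    ifelse(age_cod == "DEC", age_years / 10,
                           age_years * 12))
  age_val[age_missing] <- NA_real_
  age_cod[age_missing] <- NA_character_
  wt_kg <- pmin(pmax(round(rnorm(n, spec$weight_mean, spec$weight_sd), 1),
                     30), 160)
  wt_missing <- runif(n) < spec$weight_missing
  wt_cod <- sample(c("KG", "LBS"), n, replace = TRUE, prob = c(0.8, 0.2))
  wt_val <- round(ifelse(wt_cod == "KG", wt_kg, wt_kg / 0.45359237), 1)
  wt_val[wt_missing] <- NA_real_
  wt_cod[wt_missing] <- NA_character_
  country <- .sample_cat(n, spec$countries)
  occp <- .sample_cat(n, spec$reporters)
  outc <- .sample_cat(n, spec$outcomes)

  # dates: FDA receipt uniform over quarters; event precedes receipt;
  # therapy start precedes the event by the Weibull onset lag
  qt <- config$quarters[sample.int(length(config$quarters), n, replace = TRUE)]
  q_start <- as.Date(sprintf("%s-%02d-01", substr(qt, 1, 4),
                             (as.integer(substr(qt, 6, 6)) - 1L) * 3L + 1L),
                     format = "%Y-%m-%d")
  fda_dt <- q_start + sample.int(89, n, replace = TRUE) - 1L
  event_dt <- fda_dt - sample.int(90, n, replace = TRUE)
  lag_days <- pmax(round(rweibull(n, config$onset_shape,
                                  config$onset_scale_days)), 0)
  start_dt <- event_dt - lag_days
  event_missing <- runif(n) < config$p_event_date_missing
  ther_missing <- runif(n) < config$p_ther_missing

  # duplicate injection: extra case versions, later FDA dates, higher pids
  n_dup <- if (n) rbinom(1, n, config$duplicate_rate) else 0L
  dup_cases <- if (n_dup) sort(sample.int(n, n_dup)) else integer(0)
  n_versions <- rep(1L, n)
  n_versions[dup_cases] <- sample(2:3, n_dup, replace = TRUE)

  ver_row <- rep(seq_len(n), n_versions)
  ver_no <- sequence(n_versions)
  primaryid <- caseid[ver_row] * 100 + ver_no
  gap <- ifelse(ver_no == 1L, 0L,
                sample.int(120, length(ver_no), replace = TRUE))
  ver_fda <- fda_dt[ver_row] + ave(gap, ver_row, FUN = cumsum)

  fmt <- function(d) as.integer(format(d, "%Y%m%d"))
  ver_quarter <- paste0(format(ver_fda, "%Y"), "Q",
                        (as.integer(format(ver_fda, "%m")) - 1) %/% 3 + 1)

  demo <- data.table(
    primaryid = primaryid, caseid = caseid[ver_row], caseversion = ver_no,
    fda_dt = fmt(ver_fda),
    event_dt = ifelse(event_missing[ver_row], NA_integer_,
                      fmt(event_dt[ver_row])),
    age = age_val[ver_row], age_cod = age_cod[ver_row],
    sex = sex[ver_row], wt = wt_val[ver_row], wt_cod = wt_cod[ver_row],
    occp_cod = occp[ver_row], occr_country = country[ver_row],
    quarter = ver_quarter)

  ver_dt <- data.table(caseid = caseid[ver_row], primaryid = primaryid,
                       quarter = ver_quarter)
  drug <- data.table(caseid = caseid, drugname = drug_names[drug_idx],
                     role_cod = "PS", drug_seq = 1L)[
    ver_dt, on = "caseid", allow.cartesian = TRUE]
  # a second, concomitant drug on ~20% of reports exercises role filtering
  conc <- which(runif(n) < 0.2)
  if (length(conc)) {
    conc_rows <- data.table(
      caseid = caseid[conc],
      drugname = drug_names[(drug_idx[conc] %% config$n_drugs) + 1L],
      role_cod = "C", drug_seq = 2L)[ver_dt, on = "caseid",
                                     allow.cartesian = TRUE]
    drug <- rbind(drug, conc_rows)
  }
  setorder(drug, caseid, primaryid, drug_seq)
  drug <- drug[, .(primaryid, caseid, drug_seq, role_cod, drugname,
                   quarter)]

  reac <- reac0[ver_dt, on = "caseid", allow.cartesian = TRUE,
                nomatch = NULL]
  reac[, pt := ev_names[event]]
  setorder(reac, caseid, primaryid, event)
  reac <- reac[, .(primaryid, caseid, pt, quarter)]

  outc_dt <- data.table(caseid = caseid, outc_cod = outc)[
    ver_dt, on = "caseid", allow.cartesian = TRUE]
  setorder(outc_dt, caseid, primaryid)
  outc_dt <- outc_dt[, .(primaryid, caseid, outc_cod, quarter)]

  ther <- data.table(
    caseid = caseid, dsg_drug_seq = 1L,
    start_dt = ifelse(ther_missing, NA_integer_, fmt(start_dt)))[
    ver_dt, on = "caseid", allow.cartesian = TRUE]
  setorder(ther, caseid, primaryid)
  ther <- ther[, .(primaryid, caseid, dsg_drug_seq, start_dt, quarter)]

  canonical <- data.table(caseid = caseid,
                          primaryid = caseid * 100 + n_versions)
  truth <- list(
    planted_rr = config$planted_rr,
    onset_shape = config$onset_shape,
    onset_scale_days = config$onset_scale_days,
    duplicate_map = ver_dt[, .(caseid, primaryid)],
    canonical_version = canonical,
    reports = data.table(
      caseid = caseid, primaryid = canonical$primaryid,
      drug = drug_names[drug_idx], is_target = drug_idx == 1L,
      lag_days = lag_days,
      lag_observed = !event_missing & !ther_missing,
      sex = sex, age_years = ifelse(age_missing, NA_real_, age_years),
      weight_kg = ifelse(wt_missing, NA_real_, wt_kg)),
    event_names = ev_names,
    target_drug = config$target_drug)

  list(tables = list(demo = demo, drug = drug, reac = reac,
                     outc = outc_dt, ther = ther),
       truth = truth)
}

#' Write a simulated bundle to disk
#'
#' Writes the five quarterly ASCII tables plus a `ground_truth.json`
#' sidecar with the planted parameters and bookkeeping.
#'
#' @param sim result of [simulate_reports()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_sim_bundle <- function(sim, dir) {
  paths <- write_faers_ascii(sim$tables, dir)
  gt <- sim$truth
  gt$duplicate_map <- as.data.frame(gt$duplicate_map)
  gt$canonical_version <- as.data.frame(gt$canonical_version)
  gt$reports <- as.data.frame(gt$reports)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, truth_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(paths, truth_path))
}
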