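# Ingest: deduplication of case versions, primary-suspect screening, and
# assembly of analysis-ready report records from the raw quarterly tables.

.age_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                 DY = 1 / 365.25, HR = 1 / 8766)

.occp_map <- c(CN = "consumer", MD = "physician",
               OT = "other health professional",
               HP = "other health professional",
               RN = "other health professional",
               PH = "pharmacist")

.outc_map <- c(CA = "congenital anomaly", DE = "death", DS = "disability",
               HO = "hospitalization", LT = "life-threatening",
               OT = "other")

#' Deduplicate spontaneous-report case versions
#'
#' FAERS distributes successive versions of the same case (same Case ID)
#' across quarters. Following the FDA-recommended cleaning rule, for each
#' Case ID the version with the latest FDA receipt date is retained; when
#' FDA dates tie, the version with the highest Primary ID wins. Rows with a
#' missing FDA date lose to any dated version. The operation is idempotent
#' and never invents rows.
#'
#' @param demo DEMO table (data.frame) with columns `primaryid`, `caseid`,
#'   `fda_dt`.
#' @return `data.table` with exactly one row per `caseid`, sorted by
#'   `caseid`.
#' @export
deduplicate <- function(demo) {
  demo <- as.data.table(demo)
  if (nrow(demo) == 0) return(demo)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  setorderv(demo, c("caseid", "fda_dt", "primaryid"), na.last = FALSE)
  out <- demo[demo[, .I[.N], by = caseid]$V1]
  setorder(out, caseid)
  out[]
}

#' Select reports where a target drug appears with a given role
#'
#' Drug names are matched exactly after normalization (case-folding,
#' trimming, collapsing internal whitespace) against the synonym list;
#' substring matching is deliberately not used, to avoid capturing
#' combination-product strings.
#'
#' @param drug DRUG table with columns `primaryid`, `drugname`, `role_cod`.
#' @param synonyms non-empty character vector of drug names.
#' @param roles FAERS role codes to accept (default `"PS"`, primary
#'   suspect; the full set is PS, SS, C, I).
#' @return sorted vector of unique `primaryid`s.
#' @export
select_target_reports <- function(drug, synonyms, roles = "PS") {
  if (length(synonyms) == 0) stop("synonym list must be non-empty")
  stopifnot(all(roles %in% c("PS", "SS", "C", "I")))
  drug <- as.data.table(drug)
  syn <- normalize_term(synonyms)
  hit <- drug[normalize_term(drugname) %chin% syn & role_cod %in% roles]
  sort(unique(hit$primaryid))
}

.convert_age_years <- function(age, age_cod) {
  f <- .age_factor[toupper(age_cod)]
  f[is.na(age_cod)] <- 1  # unit missing: assume years, the FAERS default
  yrs <- age * f
  implausible <- !is.na(yrs) & (yrs < 0 | yrs > 120)
  if (any(implausible)) {
    warning(sum(implausible),
            " implausible age(s) (>120 years or negative) set missing")
    yrs[implausible] <- NA_real_
  }
  yrs
}

.convert_weight_kg <- function(wt, wt_cod) {
  unit <- toupper(wt_cod)
  f <- ifelse(is.na(unit) | unit == "KG" | unit == "KGS", 1,
              ifelse(unit == "LBS" | unit == "LB", 0.45359237,
                     ifelse(unit == "GMS", 1e-3, NA_real_)))
  kg <- wt * f
  bad <- !is.na(kg) & (kg <= 0 | kg > 500)
  if (any(bad)) {
    warning(sum(bad), " implausible weight(s) set missing")
    kg[bad] <- NA_real_
  }
  kg
}

#' Assemble analysis-ready records for a deduplicated cohort
#'
#' Joins reactions, drugs, outcomes and therapy dates onto the surviving
#' case versions, normalizes age and weight units (decades, months, weeks,
#' days, hours to years; pounds to kilograms), maps reporter-occupation and
#' outcome codes to labels, and collapses outcomes to one sorted,
#' comma-separated set per report. Reaction or drug rows referencing a
#' superseded case version are dropped (they belong to an earlier version
#' of the case); reports with zero reactions are retained and counted.
#'
#' @param tables list as returned by [read_faers_ascii()].
#' @param target_ids `primaryid`s defining the cohort (e.g. from
#'   [select_target_reports()]); after deduplication, only surviving ids
#'   are kept.
#' @param dedup_demo optional pre-deduplicated DEMO table; by default
#'   [deduplicate()] is applied to `tables$demo`.
#' @return list with
#'   `reports` (one row per cohort report: demographics, dates, outcomes),
#'   `reactions` (`primaryid`, `pt`; unique pairs),
#'   `drugs` (`primaryid`, `drug_name_raw`, `role`, `therapy_start_date`),
#'   `background_ids` (all deduplicated report ids, target and not),
#'   `background_reactions` (unique report-PT pairs for all deduplicated
#'   reports), and `log` (counts of pruned rows and zero-reaction reports).
#' @export
assemble_records <- function(tables, target_ids, dedup_demo = NULL) {
  demo <- if (is.null(dedup_demo)) deduplicate(tables$demo) else
    as.data.table(dedup_demo)
  surviving <- demo$primaryid
  target_ids <- intersect(target_ids, surviving)

  reac_all <- as.data.table(tables$reac)[primaryid %in% surviving]
  n_pruned_reac <- nrow(tables$reac) - nrow(reac_all)
  reac_all <- unique(reac_all[!is.na(pt), .(primaryid, pt)])

  ther <- as.data.table(tables$ther)[, .(primaryid, dsg_drug_seq, start_dt)]
  drugs <- as.data.table(tables$drug)[primaryid %in% target_ids]
  drugs <- merge(drugs, ther,
                 by.x = c("primaryid", "drug_seq"),
                 by.y = c("primaryid", "dsg_drug_seq"),
                 all.x = TRUE, sort = FALSE)
  drugs <- drugs[, .(primaryid, drug_name_raw = drugname, role = role_cod,
                     therapy_start_date = faers_date(start_dt))]
  setorder(drugs, primaryid, role, drug_name_raw)

  outc <- as.data.table(tables$outc)[primaryid %in% target_ids]
  outc[, outc_cod := .outc_map[toupper(outc_cod)]]
  outc_set <- outc[!is.na(outc_cod),
                   .(outcomes = paste(sort(unique(outc_cod)),
                                      collapse = ";")),
                   by = primaryid]

  dt <- demo[primaryid %in% target_ids]
  reports <- data.table(
    primaryid = dt$primaryid,
    caseid = dt$caseid,
    fda_date = faers_date(dt$fda_dt),
    event_date = faers_date(dt$event_dt),
    sex = ifelse(dt$sex %in% c("F", "M"),
                 c(F = "female", M = "male")[dt$sex], NA_character_),
    age_years = .convert_age_years(dt$age, dt$age_cod),
    weight_kg = .convert_weight_kg(dt$wt, dt$wt_cod),
    country = dt$occr_country,
    reporter = unname(.occp_map[toupper(dt$occp_cod)]))
  reports <- merge(reports, outc_set, by = "primaryid", all.x = TRUE,
                   sort = TRUE)

  reactions <- reac_all[primaryid %in% target_ids]
  n_zero_reac <- sum(!reports$primaryid %in% reactions$primaryid)

  list(reports = reports,
       reactions = reactions,
       drugs = drugs,
       background_ids = sort(surviving),
       background_reactions = reac_all,
       log = list(n_background = length(surviving),
                  n_cohort = nrow(reports),
                  n_pruned_reactions = n_pruned_reac,
                  n_zero_reaction_reports = n_zero_reac))
}
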