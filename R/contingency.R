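# 2x2 contingency construction: the substrate of all four
# disproportionality algorithms. For each event,
#   a = target-drug reports mentioning it, b = target reports without it,
#   c = other reports with it,            d = other reports without it.
# Counting unit: unique (report, PT) pairs, so a PT repeated within one
# report counts once; at SOC level a report contributes once per SOC no
# matter how many of its PTs map there.

#' Build per-event 2x2 contingency cells
#'
#' @param reactions unique report-PT pairs (`primaryid`, `pt`) for all
#'   deduplicated reports in the loaded quarters, target and non-target
#'   (e.g. `background_reactions` from [assemble_records()]).
#' @param target_ids `primaryid`s of the target-drug cohort.
#' @param background_ids `primaryid`s of all deduplicated reports
#'   (must contain `target_ids`); reports with zero reactions still count
#'   in the margins.
#' @param level `"PT"` (default) or `"SOC"`.
#' @param pt_soc PT-to-SOC map (required when `level = "SOC"`).
#' @return `data.table` with one row per event: `event`, `a`, `b`, `c`,
#'   `d`, `N`, and the expected count `E = (a+b)(a+c)/N` used by the
#'   empirical-Bayes shrinker.
#' @export
build_cells <- function(reactions, target_ids, background_ids,
                        level = c("PT", "SOC"), pt_soc = NULL) {
  level <- match.arg(level)
  if (length(background_ids) == 0) stop("empty background: no reports")
  if (!all(target_ids %in% background_ids)) {
    stop("target_ids must be a subset of background_ids")
  }
  reac <- as.data.table(reactions)[, .(primaryid, pt)]
  if (level == "SOC") {
    if (is.null(pt_soc)) stop("a PT->SOC map is required at SOC level")
    reac[, pt := map_pt_to_soc(pt, pt_soc)]
  }
  reac <- unique(reac)
  n_target <- length(unique(target_ids))
  n_total <- length(unique(background_ids))
  reac[, tgt := primaryid %in% target_ids]
  cells <- reac[, .(a = sum(tgt), total = .N), by = .(event = pt)]
  cells[, `:=`(b = n_target - a, c = total - a)]
  cells[, d := (n_total - n_target) - c]
  cells[, `:=`(N = n_total, E = n_target * total / n_total)]
  cells[, total := NULL]
  setorder(cells, -a, event)
  cells[]
}
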