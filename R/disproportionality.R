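# The frequentist pair of disproportionality statistics (ROR, PRR) and the
# Bayesian information component, plus the combined positive-signal rule.
#
# Zero-cell policy: by default a cell with any zero among a, b, c, d yields
# undefined ROR/PRR (encoded NA, flag false) rather than a Haldane +0.5
# corrected value; corrections move flags, so they are opt-in.

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ror = (a d)/(b c)` with the log-normal 95% interval
#' `exp(log ror +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d contingency counts (vectorized).
#' @param zero_policy `"undefined"` (default): any zero count yields `NA`;
#'   `"haldane"`: add 0.5 to all four counts of affected cells.
#' @param conf confidence level (default 0.95).
#' @return `data.table` with columns `ror`, `ror_lo95`, `ror_hi95`.
#' @export
ror_stats <- function(a, b, c, d, zero_policy = c("undefined", "haldane"),
                      conf = 0.95) {
  zero_policy <- match.arg(zero_policy)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  z <- qnorm(1 - (1 - conf) / 2)
  has0 <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_policy == "haldane") {
    a <- a + 0.5 * has0; b <- b + 0.5 * has0
    c <- c + 0.5 * has0; d <- d + 0.5 * has0
    has0 <- rep(FALSE, length(a))
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- data.table(ror = ror,
                    ror_lo95 = exp(log(ror) - z * se),
                    ror_hi95 = exp(log(ror) + z * se))
  out[has0, c("ror", "ror_lo95", "ror_hi95") := NA_real_]
  out[]
}

#' Proportional reporting ratio with Pearson chi-square
#'
#' `prr = [a/(a+b)] / [c/(c+d)]`; the accompanying statistic is the
#' Pearson chi-square of the 2x2 table, without continuity correction by
#' default (`correction = TRUE` applies Yates).
#'
#' @inheritParams ror_stats
#' @param correction apply the Yates continuity correction (default
#'   `FALSE`).
#' @return `data.table` with columns `prr`, `prr_chisq`.
#' @export
prr_stats <- function(a, b, c, d, zero_policy = c("undefined", "haldane"),
                      correction = FALSE) {
  zero_policy <- match.arg(zero_policy)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  undef <- c == 0 | (a + b) == 0 | (c + d) == 0 | a == 0
  if (zero_policy == "haldane") {
    shift <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * shift; b <- b + 0.5 * shift
    c <- c + 0.5 * shift; d <- d + 0.5 * shift
    undef <- rep(FALSE, length(a))
  }
  prr <- (a / (a + b)) / (c / (c + d))
  N <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (correction) dev <- pmax(dev - N / 2, 0)
  chisq <- N * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  out <- data.table(prr = prr, prr_chisq = chisq)
  out[undef, prr := NA_real_]
  out[]
}

# Exact cumulants of log2 p for p ~ Beta(s, t): mean via digamma, variance
# via trigamma, third central moment via psigamma(, 2).
.log2beta_cumulants <- function(s, t) {
  list(m = (digamma(s) - digamma(s + t)) / log(2),
       v = (trigamma(s) - trigamma(s + t)) / log(2)^2,
       k3 = (psigamma(s, 2) - psigamma(s + t, 2)) / log(2)^3)
}

#' Information component (BCPNN) with closed-form credible bound
#'
#' The point estimate is the simplified information component
#' `ic = log2( a N / ((a+b)(a+c)) )`, i.e. the log2 ratio of the observed
#' to the expected joint reporting probability; it is undefined (NA) when
#' `a = 0`. The credible bound treats the three probabilities
#' `p(drug, event)`, `p(drug)`, `p(event)` as independent
#' `Beta(x + 1, N - x + 1)` posteriors (uniform priors), computes the
#' exact mean, variance and third cumulant of `ic` on the log2 scale via
#' polygamma functions, and applies a Cornish-Fisher-adjusted normal
#' quantile. Tests guard this closed form against Monte-Carlo sampling of
#' the same posterior.
#'
#' @inheritParams ror_stats
#' @param q lower credible-quantile level (default 0.025 for IC025).
#' @return `data.table` with columns `ic`, `ic025`.
#' @export
bcpnn_stats <- function(a, b, c, d, q = 0.025) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ic <- ifelse(a > 0, log2(a * N / ((a + b) * (a + c))), NA_real_)
  cxy <- .log2beta_cumulants(a + 1, N - a + 1)
  cx <- .log2beta_cumulants(a + b + 1, N - (a + b) + 1)
  cy <- .log2beta_cumulants(a + c + 1, N - (a + c) + 1)
  mu <- cxy$m - cx$m - cy$m
  va <- cxy$v + cx$v + cy$v
  k3 <- cxy$k3 - cx$k3 - cy$k3
  z <- qnorm(q)
  zc <- z + (k3 / va^1.5) / 6 * (z^2 - 1)
  data.table(ic = ic, ic025 = mu + zc * sqrt(va))
}

#' Apply per-algorithm signal criteria and the combined rule
#'
#' Default criteria: ROR `a >= 3` and lower 95% bound `> 1`; PRR `a >= 3`,
#' `prr >= 2`, `chisq >= 4`; BCPNN `ic025 > 0`; MGPS `ebgm05 > 2`. The
#' combined flag is the conjunction of all four — an event is a positive
#' signal only when every algorithm agrees. Undefined statistics never
#' flag.
#'
#' @param results `data.table` with columns `a`, `ror_lo95`, `prr`,
#'   `prr_chisq`, `ic025`, `ebgm05` (e.g. from [signal_table()]).
#' @param thresholds list from [signal_thresholds()].
#' @return input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `flag_positive` added.
#' @export
flag_signals <- function(results, thresholds = signal_thresholds()) {
  results <- as.data.table(results)
  th <- thresholds
  isT <- function(x) !is.na(x) & x
  results[, flag_ror := isT(a >= th$min_n & ror_lo95 > th$ror_lo)]
  results[, flag_prr := isT(a >= th$min_n & prr >= th$prr_min &
                              prr_chisq >= th$prr_chisq_min)]
  results[, flag_bcpnn := isT(ic025 > th$ic025_min)]
  results[, flag_mgps := isT(ebgm05 > th$ebgm05_min)]
  results[, flag_positive := flag_ror & flag_prr & flag_bcpnn & flag_mgps]
  results[]
}

#' Signal-criterion thresholds
#'
#' @param min_n minimum report count `a` for ROR and PRR flags.
#' @param ror_lo ROR lower-bound threshold (flag when `ror_lo95 > ror_lo`).
#' @param prr_min,prr_chisq_min PRR point and chi-square thresholds.
#' @param ic025_min BCPNN lower-credible-bound threshold.
#' @param ebgm05_min MGPS 5th-percentile threshold.
#' @return named list of thresholds.
#' @export
signal_thresholds <- function(min_n = 3, ror_lo = 1, prr_min = 2,
                              prr_chisq_min = 4, ic025_min = 0,
                              ebgm05_min = 2) {
  list(min_n = min_n, ror_lo = ror_lo, prr_min = prr_min,
       prr_chisq_min = prr_chisq_min, ic025_min = ic025_min,
       ebgm05_min = ebgm05_min)
}

#' Compute all four disproportionality statistics for a cell table
#'
#' Convenience wrapper: ROR, PRR + chi-square, IC + IC025, EBGM + EBGM05
#' (fitting the empirical-Bayes prior on the supplied cells unless one is
#' given), then applies [flag_signals()].
#'
#' @param cells output of [build_cells()].
#' @param prior optional [fit_mgps_prior()] result; fitted on `cells` when
#'   `NULL` and there are at least 2 cells.
#' @param thresholds see [signal_thresholds()].
#' @param zero_policy,correction passed to [ror_stats()] / [prr_stats()].
#' @return `data.table`, one row per event, with counts, statistics and
#'   flags; attribute `"mgps_prior"` carries the fitted prior.
#' @export
signal_table <- function(cells, prior = NULL,
                         thresholds = signal_thresholds(),
                         zero_policy = c("undefined", "haldane"),
                         correction = FALSE) {
  zero_policy <- match.arg(zero_policy)
  cells <- as.data.table(cells)
  if (is.null(prior)) prior <- fit_mgps_prior(cells$a, cells$E)
  res <- cbind(
    cells[, .(event, n = a, a, b, c, d, N, E)],
    ror_stats(cells$a, cells$b, cells$c, cells$d, zero_policy),
    prr_stats(cells$a, cells$b, cells$c, cells$d, zero_policy,
              correction = correction),
    bcpnn_stats(cells$a, cells$b, cells$c, cells$d),
    mgps_stats(cells$a, cells$E, prior))
  res <- flag_signals(res, thresholds)
  setattr(res, "mgps_prior", prior)
  res[]
}

#' Rank a signal table
#'
#' Stable descending sort by the chosen key; ties broken by event label in
#' lexicographic order.
#'
#' @param results a signal table.
#' @param by sort key: `"n"`, `"ror"` or `"ebgm"`.
#' @param positive_only keep only events with `flag_positive` (default
#'   `FALSE`).
#' @param top optional number of rows to keep after sorting.
#' @return sorted `data.table`.
#' @export
rank_signals <- function(results, by = c("n", "ror", "ebgm"),
                         positive_only = FALSE, top = NULL) {
  by <- match.arg(by)
  res <- as.data.table(results)
  if (positive_only) res <- res[flag_positive == TRUE]
  res <- res[order(-res[[by]], event)]
  if (!is.null(top)) res <- head(res, top)
  res[]
}
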