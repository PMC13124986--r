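---
title: "Methods: disproportionality signal detection, onset modelling and subgroup testing in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection, onset modelling and subgroup testing in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

This vignette documents the statistical models implemented in `pvsignal`,
the assumptions behind them, the tunable parameters and their defaults,
what the bundled synthetic generator does and does not emulate, and the
numerical choices that make the pipeline deterministic.

## The data model

Spontaneous-reporting databases such as FAERS distribute quarterly,
dollar-delimited ASCII tables: demographics (DEMO), drug mentions with
role codes (DRUG), MedDRA preferred-term reactions (REAC), outcomes
(OUTC) and therapy dates (THER), linked by a Primary ID. A *case* may
appear in several quarters as successive versions sharing a Case ID.
`deduplicate()` applies the FDA-recommended cleaning rule: per Case ID,
keep the version with the latest FDA receipt date, breaking ties by the
highest Primary ID. Versions with a missing receipt date lose to any
dated version — an undated record cannot be shown to be the newest. The
operation is idempotent and order-deterministic (output sorted by Case
ID), which the test suite verifies against the generator's bookkeeping.

Cohort selection matches drug names *exactly after normalization*
(case-folding, trimming, whitespace collapsing) against a synonym list,
with the role filter defaulting to primary suspect (PS). Substring
matching is deliberately avoided: combination-product strings would
otherwise be captured silently. Six trade/laboratory synonyms for
vortioxetine ship with the package; any other drug is one text file away.

Counting unit everywhere is the unique (report, PT) pair: a PT repeated
within a report counts once, and at SOC level a report contributes at
most once per SOC however many of its PTs map there. This is standard
practice and prevents multi-PT reports from inflating cells. Whether to
count per report or per drug–event row is genuinely open in the field;
per-report counting was chosen and fixed before any calibration work.

Age units are normalized to years (decades ×10, months ÷12, weeks
÷52.18, days ÷365.25, hours ÷8766; results above 120 years are set
missing with a warning), weights to kilograms (pounds × 0.45359237).
Missing demographics are retained in the cohort and excluded only from
analyses that require the field, mirroring how published cohort tables
show explicit "Missing" rows while contingency tests exclude them.

## Disproportionality statistics

All four algorithms consume the same 2×2 cell per event: `a` target
reports with the event, `b` target without, `c` non-target with, `d`
non-target without, with `N = a+b+c+d` and expected count
`E = (a+b)(a+c)/N`. The background is *all deduplicated reports in the
loaded quarters* — the package takes the data it is given as the
reporting universe rather than assuming access to the full database.

**ROR.** The cross-ratio `ad/bc` with the Woolf (log-normal) interval.
Any zero among a, b, c, d makes the statistic undefined under the
default policy; a Haldane +0.5 correction is available as an explicit
opt-in (`zero_policy = "haldane"`) because corrections move flags and
should never be silent.

**PRR.** `[a/(a+b)]/[c/(c+d)]` accompanied by the Pearson χ² of the 2×2
without continuity correction; Yates is a configuration switch. The
uncorrected default is not arbitrary: the same uncorrected statistic is
what reproduces the published subgroup contingency values exactly (see
below), and consistency across modules beats a half-unit correction
whose conservatism is anyway contested for signal screening.

**BCPNN information component.** The point estimate is the simplified
`IC = log2(aN / ((a+b)(a+c)))` — the log₂ ratio of observed to expected
joint reporting probability. This is the variant whose values line up
with how IC is printed alongside PRR in published FAERS tables (for
small-count rows, printed IC ≈ log₂ PRR, which the shifted variants do
not satisfy). At `a = 0` the point estimate is undefined (NA) and the
algorithm can never flag. For the credible bound IC025 the three
probabilities p(drug, event), p(drug), p(event) get independent
`Beta(x+1, N−x+1)` posteriors (uniform priors); on the log₂ scale the
mean, variance and third cumulant of IC are then exact polygamma
expressions, and IC025 applies a Cornish–Fisher-adjusted normal
quantile. The skew adjustment matters: a plain normal approximation
misses the Monte-Carlo 2.5th percentile by up to ~0.05 log₂-units on
moderate cells, while the adjusted form agrees to a few thousandths.
The test suite and the acceptance script keep an independent 10⁵-draw
Monte-Carlo sampler of the same posterior as a guard.

**MGPS / EBGM.** DuMouchel's empirical-Bayes model: `a ~ Poisson(λE)`
with a two-component gamma mixture prior on λ,
`λ ~ P·Gamma(α₁, β₁) + (1−P)·Gamma(α₂, β₂)`. The marginal of `a` is a
negative-binomial mixture; `fit_mgps_prior()` maximizes its likelihood
over the five hyperparameters by quasi-Newton ascent (BFGS on
log/logit-transformed parameters, relative tolerance 1e-12, parameters
boxed to |log θ| ≤ 25) from a fixed three-point multi-start — diffuse,
concentrated-at-1, and bimodal null-plus-signal — so the fit is
deterministic given the data. Direct likelihood maximization was chosen
over EM: with only five parameters and a cheap vectorized likelihood it
converges faster and to the same optimum, and determinism comes from
the fixed starts either way. The posterior of λ given `a` is again a
two-gamma mixture, giving `EBGM = 2^E[log2 λ | a]` in closed form via
digamma, and EBGM05 by bisection on the mixture CDF to 1e-6. At least
50 cells are recommended for a stable prior; the fit refuses fewer than
2\. A fit that fails to converge from every start raises an error that
carries the best-so-far parameters for diagnosis.

**Combined rule.** An event is a *positive signal* only when all four
algorithms agree: `a ≥ 3` and ROR lower bound > 1; `a ≥ 3`, PRR ≥ 2 and
χ² ≥ 4; IC025 > 0; EBGM05 > 2. Every threshold is configurable through
`signal_thresholds()`; these defaults are the thresholds conventional in
the FAERS literature. The conjunction is deliberately conservative —
under a simulated complete null (1,000 events, all relative rates 1) the
acceptance suite requires ≤ 1% positive flags, and the observed rate is
essentially zero, because EBGM05 > 2 is nearly unreachable without a
genuine signal.

## Time-to-onset modelling

Onset is the lag in days from the earliest target-drug therapy start in
a report to the event date; one lag per report, avoiding within-report
correlation. Reports missing either date, or with the event before the
start, are excluded and counted. Same-day onsets map to 0.5 days rather
than being dropped: the Weibull support is positive, and discarding the
earliest events would bias the shape upward exactly where the
early-failure question is decided.

The Weibull MLE solves the one-dimensional profile score equation for
the shape with a bracketed root search (tolerance 1e-10); powers `t^β`
are computed on a re-centred log scale so large trial shapes cannot
overflow. The scale then has a closed form. The default 95% CI for the
shape comes from the observed Fisher information with a delta-method
interval on log β (guaranteeing a positive lower bound); a seeded
percentile bootstrap (2,000 resamples) is available when the asymptotic
interval is in doubt. The published-style classification uses the CI,
not the point estimate: early failure iff the whole CI is below 1,
wear-out iff wholly above, random otherwise — a trichotomy by
construction, property-tested over random intervals.

There is no censoring model: spontaneous reports carry no at-risk
denominator, so only reports with observed events enter. The fitted
shape therefore describes the distribution of *reported* onsets, not a
hazard in a defined cohort — an inherent limitation of the data source,
shared by all published analyses of this kind.

## Subgroup testing

`subgroup_test()` takes an r×2 category-by-suicide-status count matrix.
The default is Pearson's χ² without continuity correction; under the
`"auto"` policy it switches to Fisher's exact test when any expected
count falls below 5 (the conventional threshold — the literature this
package follows states the either/or without a rule, so the threshold is
explicit and configurable). All-zero category rows are dropped with a
warning and the degrees of freedom adjusted. The choice of the
*uncorrected* statistic is verified, not assumed: feeding the published
sex/age/weight contingency tables through this code reproduces the
printed χ² values (48.77, 30.17, 0.88) to the printed precision, which
the Yates-corrected statistic does not.

Age re-binning supports both the descriptive scheme (<18, 18–64, 65–85,
>85) and the FDA boxed-warning strata (≤24, 25–64, ≥65), with boundary
ages assigned to the lower-bounded bin containing them (24.0 → "≤24").

## The synthetic generator

`simulate_reports()` emulates exactly the ingredients the pipeline
consumes, with known ground truth:

* each case draws one suspect drug uniformly; each PT occurs
  independently with probability `baseline_prob × events_per_report ×
  rr(drug, event)`, capped at 1 with a warning. The Bernoulli design
  makes the empirical rate ratio converge to the planted `rr` exactly,
  so planted signals are recoverable oracles rather than approximations;
* a `duplicate_rate` fraction of cases is emitted as 2–3 versions with
  strictly increasing FDA dates and Primary IDs and *identical*
  demographics, isolating the deduplication rule under test;
* onset lags are Weibull with shape 0.58 and scale 60 days by default —
  the early-failure profile reported for vortioxetine, with a scale
  giving a median near the observed two-to-three weeks;
* demographic marginals default to the shape of a consumer-dominated
  antidepressant cohort: 60.8% female / 26.6% male / 12.6% missing sex,
  ~50% missing age, ~80% missing weight, US-dominated countries, and
  outcome frequencies matching such a cohort; 10% of ages and 20% of
  weights are coded in non-year/non-kg units to exercise conversion;
* event names come from a bundled 30-PT, 5-SOC *synthetic* dictionary
  (including the seven suicide-related PTs under the psychiatric SOC);
  beyond 30 events, generated `PT_xxxx` names are mapped round-robin.

The generator does **not** emulate reporter-country effects, dose,
indication, concomitant-drug interaction structure, secular reporting
trends, or masking/competition between signals. Passing tests therefore
demonstrate algorithmic correctness and calibration under a clean
reporting model — not robustness to the confounding (notably
confounding by indication) that real spontaneous data carry.

## Problem sizes and determinism

The test and acceptance workloads use: 50,000–60,000 simulated reports
for rate-ratio recovery and null calibration (1,000 events for the
null), 10,000 cases with 25% duplicates for deduplication exactness, 200
replicates of n = 2,000 for Weibull shape recovery and CI coverage, 10⁵
Monte-Carlo draws for the IC025 oracle, and 20 fixed cells against the
EBGM quadrature oracle. These sizes make the law-of-large-numbers
tolerances (±20% on empirical rate ratios, ±0.02 on the mean recovered
shape) comfortably attainable while keeping a full run in minutes on one
core.

Everything downstream of the generator is deterministic: fixed
multi-start optimization, closed-form or root-found statistics, stable
sorts with lexicographic tie-breaks on event labels, and seeded
resampling where the bootstrap is requested. Running the pipeline twice
on the same inputs produces byte-identical output tables, which is
asserted end-to-end in the suite.

## Known limitations

* Disproportionality measures are reporting associations, not risks; no
  causal reading is supported, and confounding by indication is
  untouched (for an antidepressant, the treated disease itself carries
  suicidality).
* The background N is the loaded quarters, not all of FAERS; absolute
  values of the statistics shift with the background even though flags
  are designed to be robust to it.
* No stratified or masking-adjusted variants of MGPS/BCPNN.
* The XML FAERS dialect, indication-based filtering and RxNorm drug
  normalization are out of scope; the PT→SOC map must be supplied by
  the user (MedDRA licensing).
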