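# pvsignal

Disproportionality-based signal detection for spontaneous adverse-event
reports, built around the FAERS (FDA Adverse Event Reporting System)
quarterly ASCII distribution. The package grew out of a pharmacovigilance
analysis of suicide-related reporting under the antidepressant
vortioxetine, but every stage is drug-agnostic: you supply the drug
synonym list, a MedDRA PT→SOC map, and the quarterly tables.

It is aimed at pharmacovigilance analysts and biostatisticians who want a
tested, reproducible R implementation of the standard FAERS pipeline
rather than ad-hoc spreadsheet arithmetic:

1. **Ingest & clean** — parse the dollar-delimited DEMO/DRUG/REAC/OUTC/THER
   tables; deduplicate case versions by the FDA-recommended rule (keep the
   latest `FDA_DT` per Case ID, ties broken by highest Primary ID); select
   reports where the target drug is the primary suspect (PS); normalize
   age/weight units.
2. **Disproportionality** — per-event 2×2 tables (a, b, c, d) at MedDRA
   PT and SOC level, then four algorithms with their conventional
   published definitions:
   - **ROR** = ad/bc with the Woolf interval
     exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d));
   - **PRR** = [a/(a+b)] / [c/(c+d)] with the uncorrected Pearson χ² of
     the 2×2;
   - **BCPNN information component** IC = log₂(aN/((a+b)(a+c))), with a
     closed-form IC025 from the exact polygamma cumulants of the Beta
     posteriors of the three reporting probabilities;
   - **MGPS** empirical Bayes: a ~ Poisson(λE) with a two-component gamma
     mixture prior on λ fitted by marginal maximum likelihood; EBGM is the
     posterior geometric mean of λ, EBGM05 its 5th percentile.

   A **positive signal** requires all four criteria at once
   (default: a ≥ 3 & ROR lower bound > 1; a ≥ 3 & PRR ≥ 2 & χ² ≥ 4;
   IC025 > 0; EBGM05 > 2).
3. **Time to onset** — days from the earliest target-drug therapy start to
   the event; median/IQR plus a maximum-likelihood Weibull fit. The shape
   β classifies the hazard: *early failure* (95% CI below 1), *random
   failure* (CI contains 1), *wear-out failure* (CI above 1).
4. **Subgroups** — descriptive characterization (sex, age bins, weight
   bins, country, reporter, outcomes, year) and r×2 contingency tests of
   suicide-related reporting vs. demographics (uncorrected Pearson χ²,
   switching to Fisher's exact test when an expected count drops below 5).

A synthetic FAERS-like generator (`simulate_reports()`) with planted
relative reporting rates, injected duplicate case versions and
Weibull-distributed onset lags provides ground truth for every stage, so
the whole pipeline is testable without downloading the database. MedDRA
is licensed and is **not** bundled; a 30-PT synthetic dictionary stands in
for tests and examples.

## Worked example

```r
library(pvsignal)
library(data.table)

## simulate a small FAERS-like bundle with two planted signals
cfg <- sim_config(n_reports = 20000, seed = 42, duplicate_rate = 0.1,
                  planted_rr = data.frame(drug = 1, event = c(20, 28),
                                          rr = c(4, 8)))
sim <- simulate_reports(cfg)
dir <- file.path(tempdir(), "faers_demo")
write_sim_bundle(sim, dir)
fwrite(sim_pt_soc_map(30), file.path(dir, "pt_soc.tsv"), sep = "\t")

## run the full pipeline
cfg_run <- pipeline_config(dir, synonyms = pv_vortioxetine_synonyms(),
                           pt_soc = file.path(dir, "pt_soc.tsv"))
res <- run_pipeline(cfg_run)

str(res$manifest$counts)
#> $ demo_rows_read      : int 23001
#> $ reports_after_dedup : int 20000
#> $ duplicates_removed  : int 3001
#> $ target_reports      : int 1007
#> ...
#> $ positive_pt_signals : int 2

rank_signals(res$signals_pt, by = "ror", positive_only = TRUE)[,
  .(event, n, ror = round(ror, 2), prr = round(prr, 2),
    ic = round(ic, 2), ebgm = round(ebgm, 2))]
#>        event     n   ror  prr   ic ebgm
#> 1:  Pruritus   368 11.01 7.35 2.48 5.50
#> 2: Dizziness   248  4.77 3.84 1.75 3.41

res$tto
#> Weibull time-to-onset fit (n = 643)
#>   median 31.0 days (IQR 7.0-96.0)
#>   shape 0.610 (95% CI 0.575-0.647), scale 56.7 days
#>   pattern: early failure
```

The two planted drug–event pairs (relative reporting rates 4 and 8) are
the only PTs flagged positive by the all-four rule, and the Weibull fit
recovers the generator's early-failure onset profile (true shape 0.58,
scale 60 days): the point estimate is inside sampling error and the CI
sits wholly below 1, so risk is concentrated early in therapy. Note that
the ROR (11.01) exceeds the planted relative rate (8) for Pruritus — an
odds ratio always exceeds the corresponding proportion ratio when the
event is common in the exposed group.

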