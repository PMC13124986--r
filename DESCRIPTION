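Package: pvsignal
Title: Pharmacovigilance Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the FAERS quarterly ASCII format:
    case-version deduplication, primary-suspect drug screening, 2x2
    contingency construction at MedDRA preferred-term and system-organ-class
    level, four signal-detection algorithms (reporting odds ratio,
    proportional reporting ratio with Pearson chi-square, Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma Poisson shrinker with an empirical-Bayes two-gamma mixture prior)
    combined into a single positive-signal rule, Weibull time-to-onset
    modelling with hazard-pattern classification, and demographic subgroup
    contingency testing. A synthetic FAERS-like report generator with known
    ground truth (planted reporting rates, injected duplicate case versions,
    Weibull onset lags) makes every stage testable without access to the
    live database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
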