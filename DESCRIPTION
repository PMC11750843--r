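Package: faersignal
Title: Safety-Signal Mining for Combination Versus Monotherapy in Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads, validates and deduplicates FAERS-style quarterly ASCII
    tables into per-report records, assigns reports to drug-A-only,
    drug-B-only or combination cohorts from drug role codes, and screens
    tumor-related preferred terms for disproportionality signals with four
    algorithms (reporting odds ratio, proportional reporting ratio, the
    BCPNN information component and the multi-item gamma-Poisson shrinker)
    combined under a conjunction significance rule. Also provides logistic
    risk-factor comparison across cohorts, time-to-onset characterization
    (Weibull shape-parameter failure-type classification, rank-sum and
    log-rank comparisons, cumulative incidence), a fully parameterized
    synthetic spontaneous-report generator with ground truth for end-to-end
    validation, and a pipeline orchestrator that emits machine-readable
    result tables with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
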