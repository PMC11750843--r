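# faersignal

Safety-signal mining for **combination versus monotherapy** comparisons in
spontaneous adverse-event report databases of the FAERS family.

Pharmacovigilance analysts routinely ask whether co-prescribing two drugs
(here, by default, the TNF-α inhibitor infliximab together with the
immunosuppressant azathioprine) changes the reporting profile of a class
of adverse events — in this package's focus, tumor-related events —
relative to either drug alone. `faersignal` turns that question into a
tested, reusable pipeline:

* **Ingestion** of quarterly `$`-delimited ASCII tables (DEMO, DRUG,
  REAC, OUTC, THER, INDI, RPSR), with unit conversion, plausibility
  windows, and keep-latest-case-version deduplication.
* **Cohorting** from the drug role codes: `A_only` (A as primary suspect,
  no B in any role), `B_only` (symmetric), `A_plus_B` (either as primary
  suspect with the other in any role), `excluded` otherwise; reactions
  restricted to a tumor preferred-term lexicon.
* **Disproportionality screening** of every (cohort, preferred-term)
  pair against the case/non-case background on the 2×2 table
  `a, b, c, d`, with four algorithms:
  - reporting odds ratio `ROR = ad/bc` (signal: `a ≥ 3`, 95% lower
    bound `> 1`),
  - proportional reporting ratio `PRR = [a/(a+b)]/[c/(c+d)]` with the
    Pearson χ² (signal: `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`),
  - the BCPNN information component `IC = log2 p11/(p1·p·1)` with exact
    closed-form posterior moments (signal: `IC025 > 0`),
  - the multi-item gamma-Poisson shrinker: empirical-Bayes geometric
    mean `EBGM = 2^E[log2 λ|a]` under a fitted two-component gamma
    mixture prior on the relative reporting rate λ (signal: `EB05 > 2`).

  A pair is a **significant signal** only when *all four* criteria hold
  simultaneously (conjunction rule).
* **Risk-factor comparison** by univariate and multivariate logistic
  regression of tumor-signal occurrence on sex, age band, weight band
  and treatment group (univariate p < 0.05 gate for the joint model).
* **Time to onset**: event date minus therapy start, Weibull
  shape-parameter failure-type classification (early / random /
  wear-out), rank-sum comparison with exact enumeration at small n,
  cumulative incidence with the log-rank test.
* A **synthetic spontaneous-report generator** that writes complete
  FAERS-dialect quarters with exact ground truth (planted signals,
  per-cohort Weibull onset models, duplicates, missingness), so every
  stage is testable end to end without downloading anything.

## Worked example

Generate a synthetic universe of 20,000 reports in which two tumor terms
are reported tenfold above baseline in the combination cohort, then run
the scan:

```r
library(faersignal)

cfg <- synth_config(n_reports = 20000, tumor_pt_rate = 0.005,
                    seed = 20240601,
                    planted_signals = data.frame(
                      group = "A_plus_B",
                      pt = c("Anal cancer", "Basal cell carcinoma"),
                      lambda = 10))
gen <- generate_quarter(cfg, "synth_quarter")

reports <- deduplicate(read_quarter(gen$paths, "2024Q2"),
                       lexicon = read_lexicon())
asg <- assign_group(reports,
                    read_synonyms(ingredient = "infliximab"),
                    read_synonyms(ingredient = "azathioprine"))
table(asg$group)
#>   A_only   B_only A_plus_B excluded
#>     3030      989     1564    14417

scan <- signal_scan(reports, asg, read_lexicon(), "A_plus_B")
scan[scan$significant,
     c("pt", "a", "ror", "ror_lo95", "prr", "chi2", "ic025", "ebgm", "eb05")]
#>                    pt  a  ror ror_lo95   prr chi2 ic025 ebgm eb05
#>  Basal cell carcinoma 85 10.3     7.71  9.82  371  2.07    6 5.93
#>           Anal cancer 84 11.7     8.64 11.13  402  2.15    6 5.93
```

Both planted terms — and nothing else — pass all four criteria: 85 of
the 1,564 combination-cohort reports carry basal cell carcinoma against
a background rate an order of magnitude lower, giving an ROR of 10.3
(95% CI lower bound 7.7), a PRR of 9.8 with χ² = 371, a strictly
positive IC025, and an EB05 of 5.9 after empirical-Bayes shrinkage.

Time to onset in the combination cohort follows its configured
decreasing-hazard profile:

```r
tumor <- filter_tumor_reports(reports, read_lexicon())
on <- compute_onsets(tumor, asg,
                     list(A_plus_B = read_synonyms(ingredient = "infliximab")))
weibull_fit(on$onset_days)
#> <weibull_fit> n=387 shape 0.719 [0.664, 0.777] scale 1337.6 d [1155.8, 1547.9] -> early failure
```

The shape interval sits entirely below 1, so onsets are classified as
*early failure*: the estimated hazard of a tumor report is highest soon
after therapy start and declines thereafter.

`run_all(pipeline_config(...))` executes the whole flow (characteristics
tables, per-cohort signal lists, regression forest-plot tables, onset and
cumulative-incidence tables) into an output directory with a
`manifest.json` of stage counts, input hashes and the seed. A thin
command-line wrapper lives at `inst/cli/faersignal.R`.

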