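---
title: "Methods: combination-versus-monotherapy tumor signal mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combination-versus-monotherapy tumor signal mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`faersignal` implements a complete safety-signal analysis for comparing a
two-drug combination against each monotherapy in a spontaneous-report
database of the FAERS family: cohort construction from drug role codes,
four-algorithm disproportionality screening of tumor-related preferred
terms under a conjunction rule, logistic risk-factor comparison, and
time-to-onset characterization. This vignette explains the statistical
model behind each stage, the tunable parameters, and the design decisions
a user should know about.

```{r setup}
library(faersignal)
```

## Report ingestion and deduplication

Quarterly releases arrive as `$`-delimited ASCII tables (DEMO, DRUG, REAC,
OUTC, THER, INDI, RPSR) keyed by a case identifier and a case version.
Spontaneous-report databases contain follow-up versions of the same case,
so counting reports naively inflates every statistic. `deduplicate()`
keeps, per case identifier, the row with the greatest case version,
breaking ties by latest receipt date and then by last position in file
order. This rule is deterministic and order-independent after sorting, and
applying it twice changes nothing — both properties are tested.

Demographics are normalized on ingestion:

* **Age** is converted to years from the decade / year / month / week /
  day / hour unit codes; results outside [0, 120] years become missing,
  because spontaneous reports contain unit-entry errors (an "age 780"
  with a months code is a legitimate 65-year-old; an "age 200 years" is
  not).
* **Weight** is converted to kg (LBS × 0.453592, GMS / 1000) with a
  plausibility window of (0, 500] kg.
* **Dates** accept full `YYYYMMDD` plus the partial forms `YYYYMM` and
  `YYYY`. Partial dates are kept for demographics but carry a precision
  label, and the time-to-onset stage only uses day-precision dates on
  both ends.

## Cohort construction

For target drugs A and B (by default infliximab and azathioprine, matched
case-insensitively against an editable synonym table after stripping dose
and salt tokens), each report is assigned to exactly one of four cohorts
from the FAERS role codes (PS = primary suspect, SS = secondary suspect,
C = concomitant, I = interacting):

* `A_only`: some A entry with role PS and no B entry in any role;
* `B_only`: symmetric;
* `A_plus_B`: A as PS with B in any role, or B as PS with A in any role;
* `excluded`: everything else — in particular reports where neither
  target drug is a primary suspect.

The rule is symmetric: swapping the two synonym sets swaps the two
monotherapy cohorts and fixes the combination cohort.

Reactions are restricted to a tumor lexicon — a flat preferred-term to
system-organ-class table. The package ships a fixture lexicon of 82
neoplasm terms grouped into organ-class buckets; it is a stand-in
assembled for testing, not a licensed MedDRA extract, and any
user-supplied CSV with `pt, soc` columns can replace it. Terms outside
the lexicon are retained on kept reports but flagged, so that
denominators remain interpretable.

Characteristics tables use lower-closed, upper-open age bands
(`<18, [18,45), [45,60), [60,75), >=75`) and weight bands `<50`,
`[50,100]`, `>100` kg. The closed middle weight band is deliberate: the
conventional printed labels ("50–100", "60–75") are ambiguous at their
boundaries, so the package fixes one convention and documents it.

## Disproportionality statistics

For a cohort–term pair, the 2×2 table counts `a` target-cohort reports
with the term, `b` without it, and `c`, `d` the same split over the
background — all retained reports outside the target cohort. A report
contributes at most once per term no matter how many duplicate reaction
rows it carries. The contrast that drives every statistic is the
observed-to-expected ratio `a / E` with `E = (a+b)(a+c)/N`; it is worth
noting that this contrast only has room to move when the target cohort is
a small fraction of the universe, which is why the synthetic generator's
default cohort mix keeps a large non-target background (as a real
pharmacovigilance database does).

Four statistics are computed per pair, each with the standard published
significance criterion, all exposed as configurable thresholds:

* **ROR** `= ad/bc` with the Wald interval
  `exp(log ROR ± 1.96·sqrt(1/a+1/b+1/c+1/d))`; criterion `a ≥ 3` and
  lower bound `> 1`. A 0.5 continuity correction on all four cells is
  applied only when a zero cell makes the statistic undefined, and the
  row is flagged.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson chi-square on the
  table (uncorrected by default; a Yates flag exists because both
  conventions circulate); criterion `a ≥ 3`, `PRR ≥ 2`, `χ² ≥ 4`.
* **BCPNN information component**: the posterior distribution of
  `log2(p11/(p1·p·1))` under independent beta posteriors with symmetric
  unit-style hyperpriors, the joint prior centred so the prior IC is 0.
  Because the log of a beta variable has exact digamma/trigamma moments,
  `E(IC)` and `V(IC)` are closed-form; `IC025 = E(IC) − 2·sqrt(V(IC))`
  and the criterion is `IC025 > 0`. A Monte-Carlo sampler of the same
  posterior (`bcpnn_ic_draws()`) validates the closed form in the test
  suite to within 0.05 bits.
* **MGPS / EBGM**: the relative reporting rate λ gets a two-component
  gamma mixture prior fitted by maximizing the mixture-of-negative-
  binomials marginal likelihood over all pairs (BFGS on log/logit scale
  from the start (0.2, 0.1, 2.0, 4.0, 1/3) with jittered restarts). The
  posterior is again a two-component gamma mixture;
  `EBGM = 2^E[log2 λ | a]` and `EB05` is the 5th posterior percentile
  found by root-finding the mixture CDF to 1e-8. Criterion `EB05 > 2`;
  a switch to `EBGM > 2` exists because both variants are used in
  practice.

A pair is a **significant signal** only when all four criteria hold
simultaneously. The conjunction trades sensitivity for specificity: under
the null its flag rate is bounded by the most conservative member
(empirically, near zero in the calibration tests), while a tenfold
reporting-rate elevation with a few dozen target reports passes all four
comfortably.

## Logistic risk-factor comparison

The outcome is per-report: carries at least one tumor preferred term that
the conjunction rule flagged. Covariates are categorical — sex, age band,
weight band and, in between-cohort models, the treatment group — with
reference levels female, `<18`, `<50 kg` and the combination cohort.
Missing covariate values are dropped by default (complete case); a
`missing_as_level` flag retains them as their own level instead, since
characteristics tables report missingness as a category but a regression
treating "Missing" as informative is a modeling choice the user should
opt into.

Univariate fits screen each covariate; covariates with any level at
p < 0.05 enter the joint multivariate fit ("meaningful single-factor
results" made precise as a numeric gate). Between-cohort comparisons pool
the two cohorts with a group indicator rather than matching. Fitting is
ordinary maximum-likelihood logistic regression via `glm`; the module's
own content is the design construction, gating rule, separation flagging
(diverging estimates are reported with unbounded intervals), and
forest-plot-ready output.

## Time to onset

Onset is event date minus therapy start date in days, requiring day
precision on both ends; the earliest therapy start among rows linked to a
target drug is used when several exist. Negative onsets (event before
therapy) are excluded and tallied. No censoring model is used: a
spontaneous report exists only because the event occurred, so every onset
is an observed event. This makes the "cumulative incidence" an empirical
distribution of onsets among reporters — an interpretive limitation, not
a population incidence.

The Weibull shape parameter classifies the hazard profile: the MLE is
obtained via `survival::survreg` and the 95% interval for the shape comes
from the observed-information normal approximation on the log-shape
scale. Shape interval entirely below 1 → *early failure* (decreasing
hazard); entirely above 1 → *wear-out* (increasing hazard); containing
1 → *random* (constant hazard). Classification is refused below 10
observations. Same-day onsets enter as 0.5 days since Weibull support is
positive. At the sample sizes the analysis targets (hundreds for a
monotherapy cohort, around a hundred for a combination cohort) the
classification is reliable: shape-1 samples at n = 604 classify "random"
and shape-0.7 samples at n = 112 classify "early" in the large majority
of simulation replicates, which the acceptance tests verify.

Group comparisons use the rank-sum statistic with tie correction — the
reported `z` is the standardized rank sum and the two-sided p applies the
0.5 continuity correction, which keeps the normal approximation within
0.02 of exhaustive enumeration even at 6 + 6; below 8 observations per
group the p-value is computed by full enumeration instead. Cumulative
incidence curves are compared with the log-rank test (`survival::
survdiff`). Quartiles use linear-interpolation quantiles (type 7), with
the convention switchable.

## The synthetic generator

`synth_config()` / `generate_quarter()` emit a complete FAERS-dialect
quarter (all seven tables, `$`-delimited) plus exact ground truth,
bit-reproducibly for a fixed seed. It emulates: demographic mixes with
missingness (defaults shaped like a combination-therapy cohort: ~49%
female, ~45% missing weight, ~30% missing age), role-code structures for
all four cohorts including non-qualifying mentions of the target drugs,
a preferred-term universe of 82 tumor and 30 background terms with
per-term baseline reporting rates, planted reporting-rate multipliers
per (cohort, term), per-cohort Weibull onset lags (defaults: shape 1.0 /
median ≈ 985 days for drug-A-only, shape 0.7 / median ≈ 818 days for the
combination), a 35% missing-onset fraction split between absent therapy
rows and month-precision event dates, and duplicate case versions with a
perturbed field and earlier receipt date.

The default cohort mix (15% A-only, 5% B-only, 8% combination, 72%
background) keeps every scanned cohort small relative to the universe.
What the generator does **not** emulate: reporting biases over calendar
time, correlated reactions within a report, covariate-dependent tumor
risk, or drug-name misspellings. Passing tests therefore demonstrate
that the statistical machinery is correct and calibrated on data with
the declared structure — not that any particular real-world extraction
is reproduced.

## Numerical choices and degenerate inputs

* Continuity correction (0.5 on all cells) only when a zero cell makes a
  statistic undefined, always flagged in the output row.
* MGPS prior fit: unconstrained log/logit parameterization, BFGS, best of
  the default start plus three jittered restarts; non-convergence from
  all starts is fatal with diagnostics. Likelihood evaluations that
  underflow return a large negative value rather than NaN.
* EB05 root-finding brackets the mixture CDF between 0 and the 99.9th
  percentile of both components, tolerance 1e-8.
* Empty background for a cohort, empty tumor lexicon, constant outcomes,
  degenerate onset samples (all identical) and sub-minimum onset counts
  are all explicit errors rather than silent NA propagation.
* Problem sizes in the test suite were chosen to make the statistical
  assertions sharp at modest runtime: 1,000 random tables for the
  closed-form oracles, 20 fixture tables × 10⁶–10⁷ posterior draws for
  the Bayesian oracles, 5,000 pairs for prior recovery, 200 synthetic
  universes of 10⁴ reports for null calibration, 50 universes of 6,000
  reports for planted-signal recovery, and 200 replicates per Weibull
  profile.

## Known limitations

* The tumor lexicon is a fixture; a real analysis should substitute a
  licensed MedDRA-derived term list, and the flat PT→SOC map does not
  traverse the MedDRA hierarchy.
* Disproportionality measures are reporting associations, not incidence
  or causal effects; the no-censoring onset analysis describes reporters,
  not a cohort at risk.
* One widely noted interpretive subtlety: a *random* (constant-hazard)
  Weibull profile is sometimes loosely described alongside increasing
  hazard in the applied literature; the implementation follows the
  standard shape-interval rule stated above, where constant hazard means
  shape ≈ 1.
* MGPS here is unstratified; age/sex-stratified expected counts and
  multi-drug interaction scores are out of scope.
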