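---
title: "Validating community health worker screening for puerperal sepsis: methods"
author: "ppsepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating community health worker screening for puerperal sepsis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppsepsis)
```

## The problem

Puerperal (postpartum, "PP") sepsis is a leading cause of maternal death, and
in South Asian settings most episodes occur at home, outside the reach of
facility-based diagnosis. One proposed remedy is to equip community health
workers (CHWs) conducting routine postpartum home visits with a simple
symptom-based screening algorithm, refer suspected cases, and validate the
CHW classification against physician assessment. `ppsepsis` implements that
entire validation pipeline: the rule engine itself, the kappa-family
agreement statistics used to compare CHW and physician ratings of each sign
and symptom, diagnostic validity (sensitivity/specificity with exact
intervals and verification-bias adjustment), the sample-size arithmetic of
the nested case-control design, and a synthetic surveillance cohort
generator used for end-to-end parameter-recovery checks.

## The screening algorithm

A woman's assessment occasion consists of a measured temperature (when a
thermometer reading was taken) and twelve reported/observed booleans (see
`symptom_fields()`). Classification is a deterministic rule sweep:

* **Suspected PP sepsis** — measured *high fever* (>= 39.1 °C / 102.4 °F on
  the thermometer), or a *fever signal* (measured fever 38.1-39.0 °C or a
  reported history of fever) **together with** lower abdominal/pelvic pain
  or abnormal foul-smelling discharge. This mirrors the WHO endometritis
  picture: fever plus pelvic pain or abnormal discharge.
* **Other suspected illness** — severe vaginal bleeding; severe headache
  *and* blurred vision; leaking urine/stool; convulsions or
  unconsciousness; lower abdominal pain without any fever signal.
* **Suspected local infection** — an isolated fever signal (measured
  moderate fever only, or history of fever only), afebrile abnormal
  discharge, burning on micturition, cough or difficulty breathing, wound
  pus/pain, or a swollen, red or painful breast.
* **No infection** — nothing above fires.

Two interpretive choices deserve note. First, when rules from several
categories fire simultaneously the final class is the *highest severity*
(sepsis > other illness > local infection > none); this matches the referral
logic of the surveillance programme, in which only suspected sepsis triggers
24-hour follow-up. Second, the companion symptom that upgrades a fever
signal to suspected sepsis is restricted to pain or discharge: measured
moderate fever plus a reported fever history, with neither companion, is a
*local infection* ("fever only" / "history of fever only"), not sepsis.
Both choices make the classifier monotone: turning any symptom on, or
raising the fever category, never lowers the severity — a property the test
suite verifies over the entire `2^12 x 3` input lattice against an
independently transcribed table oracle.

The fever thresholds are implemented as half-grid cuts (>= 39.05 °C for
high, >= 38.05 °C for moderate) so that the two published phrasings of the
boundary (">39.0 °C" and "39.1 °C or higher") agree for any reading reported
to one decimal place, in either unit. Missing symptom values at ingest mean
"not elicited" and are set to `FALSE`, with a warning counting affected
records (`read_assessments()`).

## Agreement statistics

The unit of analysis is the CHW-physician assessment pair, tallied into a
2x2 table per attribute (`a` both positive, `b` CHW-only, `c`
physician-only, `d` both negative; with the physician as gold standard these
are TP/FP/FN/TN). `agreement_summary()` reports:

* observed agreement `po = (a+d)/n` and chance agreement
  `pe = [(a+b)(a+c) + (c+d)(b+d)]/n^2`;
* Cohen's kappa `(po - pe)/(1 - pe)`, with the Fleiss-Cohen-Everitt
  large-sample standard error and a one-sided test of kappa > 0 using the
  null-hypothesis variance (the publication cites kappa SEs without naming
  a formula; the asymptotic SE is cross-checked against a bootstrap oracle
  in the tests);
* PABAK `= 2 po - 1`, the value kappa would take at balanced prevalence and
  zero rater bias;
* the prevalence index `|a-d|/n` and bias index `|b-c|/n` that explain the
  gap between kappa and PABAK;
* positive and negative agreement `2a/(2a+b+c)` and `2d/(2d+b+c)`.

Degenerate tables (both raters constant, or an empty conditional-agreement
denominator) yield explicit undefined markers rather than NaN, mirroring
suppressed cells in published tables.

## Diagnostic validity and verification bias

`sensitivity_specificity()` uses exact Clopper-Pearson intervals (via
`stats::binom.test`); coverage of at least 95% is verified in the tests by
exhaustive binomial enumeration for all n <= 30.

The validation design verifies *all* screen-positives but only a matched
sample of screen-negatives, so naive Se/Sp from verified subjects alone are
biased — sensitivity upward. Assuming verification depends only on the
screen result, `begg_greenes()` reweights the verified disease rates by the
population screen fractions: with `p1 = P(D+|S+)`, `p0 = P(D+|S-)` from the
verified strata and `w1 = P(S+)` from the surveillance totals,

    Se = p1 w1 / (p1 w1 + p0 w0),   Sp = (1-p0) w0 / ((1-p0) w0 + (1-p1) w1).

Under complete verification this reduces exactly to the naive estimator
(property-tested). Because no interval method is published for the adjusted
estimates, intervals are by seeded nonparametric bootstrap over verified
subjects (default 2000 replicates, percentile bounds).

The publication's headline adjusted Se 82% / Sp 90% cannot be recomputed on
the desk: the classification-level cross-tabulations behind it are not
printed. The package therefore demonstrates the estimator by *parameter
recovery* on the synthetic cohort (below), at generating values chosen to
match the published headline.

`roc_curve()` produces the empirical ROC by threshold sweep with trapezoid
AUROC; for a single binary threshold this is `(Se+Sp)/2`. The published
AUROC range (89-97%) is not reconstructible from the printed site Se/Sp
pairs and is not replicated.

## Design arithmetic

A 1:3 case:control ratio fixes the apparent sample prevalence at
`implied_prevalence(75, 225) = 0.25`. `required_sample()` uses the
normal-approximation precision formula `n = z^2 p (1-p) / m^2` per arm; at
Se 95% +/- 5% and Sp 85% +/- 15% with alpha = 0.05 it gives 73 cases and a
total of 292 at the 1:3 ratio — consistent with (and just inside) the 75
cases / 300 women actually enrolled per site. Whether the study derived its
75/300 from exactly this formula is not stated, so consistency, not
equality, is the check.

`expected_sample_prevalence()` applies Bayes' rule to show that an imperfect
screen dilutes the gold-standard prevalence of the enrolled sample below the
25% design value. That inequality is regime-bound: it holds throughout the
low-prevalence surveillance setting (population prevalence of a few
percent), but a near-perfect specificity combined with low sensitivity at a
population prevalence of 10% or more can push the sample prevalence *above*
the design value, because the cases stay pure while missed cases
contaminate the controls. The tests assert the inequality, and monotonicity
in sensitivity, only on the realistic regime (population prevalence 1-5%,
specificity >= 0.9); monotonicity in population prevalence holds generally.

## The synthetic cohort

`cohort_config()` / `run_study()` emulate the surveillance base the analysis
assumes, not any real data set:

* 10,000 women across 20 administrative clusters, visited on postpartum
  days 0, 6, 13, 20, 27, 34, 41, 48 and 59, with actual visit days
  jittered by +/- 1 day (which makes the +/- 1 day matching window
  non-trivial);
* a 5% true sepsis prevalence; infected women carry a *persistent*
  untreated episode, so their true profile satisfies the sepsis criteria at
  every visit. This is the modelling choice that makes the physician a
  coherent gold standard for infection status: a matched control assessed
  on any day shows her true state. (A short transient episode would make
  the physician miss infected-but-undetected controls assessed off-episode,
  and the "true" quantity recovered by the adjustment would no longer be
  the woman-level screening accuracy.)
* symptoms conditionally independent given infection status, at rates
  echoing the published site frequencies (`default_symptom_probs()`); a
  user-supplied joint sampler can replace the independence assumption via
  the `symptom_probs` hook;
* two CHW error layers. Per-symptom flips (`observe_profiles()`) induce the
  symptom-level disagreement that the kappa machinery quantifies.
  Classification-level screening error is imposed *by construction*: one
  per-woman draw decides whether the CHW ever recognises her (Se 0.82 for
  infected women, false alarm 1 - Sp = 0.10 for uninfected, each at one
  designated visit), and the observed fever signal is edited so that
  `classify_profiles()` on the CHW profile screens positive exactly at the
  designated visit. The algorithm is still genuinely executed on every
  CHW profile; the construction simply pins the per-woman operating
  characteristics at the configured generating values, which is what a
  parameter-recovery experiment requires. The per-woman (rather than
  per-visit) error draw reflects a CHW whose judgment of a given woman is
  stable over the short surveillance window — independent per-visit false
  alarms at 10% would make most women screen-positive across nine visits,
  which is neither the published design's regime nor a useful one for
  studying the correction.
* cases are the first 75 screen-positive women by detection day; each is
  matched to 3 controls sampled uniformly without replacement from
  never-screen-positive women of the same cluster with an assessment within
  +/- 1 day postpartum (ties among eligible controls broken uniformly at
  random; shortfalls are counted and reported, never silent);
* the physician is error-free by default (gold standard), configurable to
  study imperfect-gold-standard effects.

Randomness is a single R stream under one top-level seed; a fixed seed and
fixed configuration reproduce a study exactly. (Per-woman substreams,
which would additionally make early women invariant to population-size
changes, were deliberately traded away for vectorised draws.)

What passing recovery tests do and do not show: they validate the
estimators under the design's own assumptions — verification depending only
on screen status, cluster-homogeneous risk (which makes matched controls a
random sample of screen-negatives with respect to disease), a perfect gold
standard, conditionally independent symptoms. They do not validate
robustness to correlated symptoms, cluster-varying prevalence, imperfect
physicians, or referral non-compliance; the configuration hooks exist to
explore those, but the shipped defaults are the study conditions.

## Replicating the published tables

The packaged fixture (`fixture_path()`) transcribes the per-site 2x2 counts
(17 attributes x 3 sites; 278 + 300 + 300 = 878 pairs) and the published
reference statistics. `replicate_tables()` recomputes every statistic from
the counts and compares cell by cell: kappa and PABAK within +/- 0.01
(published values are rounded, occasionally truncated), overall agreement
within one percentage point, Se/Sp exact after round-half-up to integer
percent, interval bounds within one point (the publication's interval
method is unstated; Clopper-Pearson is used). Cells published as "-" are
excluded from the pass denominator — they are *not* uniformly undefined
computationally (one suppressed sensitivity has a defined value of 100%
from a single true positive), so the report instead records whether the
computation was defined. The published positive-agreement column is
compared informationally only; it is not reconcilable with `2a/(2a+b+c)`
for many rows.

The report's pass criterion is that at least 95% of comparable
pass-relevant cells match. On the shipped fixture the suite documents —
and itemises, row by row — a set of cells that *cannot* match because the
publication is internally inconsistent: several rows print kappa 0.00
where the printed counts show perfect agreement (kappa exactly 1), one
site's "history of fever only" row prints different statistics from
identical printed counts, one overall-agreement integer contradicts the
PABAK printed beside it, and one count had to be corrected to make its row
sum to the site total (the correction reproduces both the published
sensitivity and the published kappa of that row, so it is well
identified). Every such cell appears in `replicate_tables()$mismatches`
with both values. All interval-bound cells match within one point.

## Problem sizes and numerical choices

Test-suite and acceptance-script simulations use 200 replicate studies of
10,000 women — sizes at which the Monte Carlo error of the mean adjusted
estimates is a few thousandths, comfortably inside the +/- 0.03 recovery
band, while a full run stays in the minutes range on one core. Comparisons
against published fixed-precision values use round-half-up with a 1e-9
epsilon absorbing binary representation error; tolerance comparisons add
the same epsilon. The bootstrap for adjusted-estimate intervals defaults to
2000 replicates and is always seeded.

## Known limitations

* Strictly two-rater, binary-attribute agreement; no weighted or
  multi-rater kappa (the design needs none).
* No clustered/multilevel variance correction for the agreement or
  validity estimates (none is published for them either).
* The published five-category wording includes an "other" category that is
  never given membership criteria; the engine produces four categories and
  "other" survives only as free text at ingest.
* Etiology, treatment regimens, verbal autopsy, and the site-level
  adjusted figures whose inputs are unpublished are out of scope.
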