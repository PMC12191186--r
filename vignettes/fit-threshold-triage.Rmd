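---
title: "FIT threshold triage: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FIT threshold triage: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fittriage)
```

# The clinical model

Patients with iron-deficiency anaemia investigated for colorectal cancer
can be offered colon capsule endoscopy (CCE) instead of colonoscopy, but a
capsule examination converts to colonoscopy (CCC) whenever the findings
need tissue diagnosis or therapy. `fittriage` treats conversion as a binary
label derived from colonic findings under explicit criteria
(`conversion_criteria()`), quantifies how well the faecal haemoglobin
concentration (FIT, µg Hb/g faeces) predicts that label, and searches for
FIT thresholds at which triaging patients straight to colonoscopy is
statistically defensible and cost-effective.

## The urgent-conversion label

National CCE-to-colonoscopy referral criteria are not enumerated in a
single machine-readable source, so the label rule is configuration with a
documented default: colorectal cancer always converts; otherwise a largest
polyp of ≥ 10 mm (the standard "advanced polyp" definition) or ≥ 3 polyps
converts. Extra findings (e.g. IBD) can be added to the rule. The label is
a pure, monotone function of the findings: enlarging a polyp or adding
polyps can never un-convert a patient, and re-derivation is idempotent —
both properties are asserted in the test suite.

## Censored FIT and imputation

Quantitative FIT assays report outside their detection limits as censored
strings; sites in multicentre cohorts use assays with lower limits of
7 or 10 µg/g and a common upper limit of 400 µg/g. For modelling, censored
results are imputed *at the limit* (`"<7"` → 7, `"<10"` → 10,
`">400"` → 400). This stacks probability mass at three values, which has
two analytic consequences handled explicitly downstream: AUC uses the
tie-aware Mann–Whitney convention, and the threshold scan reports jumps at
the limits that are artefacts of the assay, not biology.

# Module-by-module statistical notes

## ROC and logistic regression

The AUC is computed as the Mann–Whitney concordance probability with ties
counted ½, via midranks. The default confidence interval is DeLong's
analytic one, computed from the placement values (the per-positive and
per-negative components of the U-statistic); a seeded stratified bootstrap
(2000 replicates, percentile interval) is available behind
`method = "bootstrap"`. DeLong was chosen as the default because it is
deterministic and exact to first order; the source analyses do not name
their CI method. Paired model comparison uses DeLong's paired test on the
difference of placement values; rank-identical scores short-circuit to
p = 1 rather than dividing by a zero variance.

Logistic models are maximum-likelihood `glm()` fits reported as odds
ratios with Wald 95% intervals and Wald p-values, matching the reporting
style of clinical studies; profile-likelihood intervals are deliberately
not implemented. Complete separation is detected heuristically (fitted
probabilities numerically 0/1 together with exploding coefficients or
standard errors) and surfaced as a warning plus a `separation` flag.
The covariate-adjusted ROC uses the multivariable model's in-sample
predicted probabilities and is flagged `apparent`: no cross-validation is
attempted, so adjusted AUCs are optimistic and the flag travels with the
result.

## CUSUM threshold scan

The scan grid is integer arithmetic in deci-µg/g units (1 unit = 0.1 µg/g)
from `floor(min FIT)` to the maximum observed FIT; FIT values are matched
to the grid by rounding to the same resolution, which is exact because the
serialisation format fixes 0.1 µg/g resolution. This removes floating-point
drift entirely: the invariant `grid[i+1] − grid[i] = 1 unit` is asserted.
A jump point is a one-step increase of at least `min_jump = 5` in the
cumulative urgent count, compared against the immediately preceding grid
point (the count below the grid start is 0).

The conversion rate at threshold t divides cumulative urgent cases by the
patients with FIT ≤ t — the subgroup a triage policy would actually send to
capsule — rather than by the whole cohort. The phrase "proportion of urgent
cases at or below each threshold" is ambiguous between those readings; the
triaged-subpopulation denominator reproduces the published order of
magnitude for low thresholds (fractions of a percent at 15 µg/g rising to
a few percent by 29 µg/g) and is therefore the default, with
`denominator = "cohort"` available. Threshold lookups refuse off-grid
values instead of snapping, because neighbouring 0.1 µg/g points can differ
by an entire imputation pile-up.

## Incremental significance scan

Group 1 is the low-FIT reference (FIT ≤ 10 µg/g); at each integer
threshold t in 11–29 µg/g the rising-FIT group is compared by logistic
regression of the urgent label on group membership. Two readings of the
rising group are implemented: cumulative, Group 2(t) = (10, t], the
default; and `group2 = "tail"`, Group 2(t) = [t, 29]. The published
description supports either; both are labelled in output. "Persistently
significant" is defined as significant at t and at every larger evaluable
threshold in the range — thresholds with an empty group or a zero cell in
the 2×2 table are flagged and skipped by the sustained-run logic rather
than breaking it. `first_sustained` is the smallest such t.

## Decision curve analysis

Net benefit at threshold probability p_t is
`TP/n − (FP/n) · p_t/(1 − p_t)`, in units of true positives per patient,
with treat-all and treat-none reference policies. The risk model is the
*univariate* FIT logistic model — the decision curve asks what acting on
FIT alone is worth. Endpoints follow the limit conventions: at p_t = 0 the
false-positive weight vanishes (treat-all net benefit = prevalence); at
p_t = 1 nobody is classified positive and net benefit is 0. Because the
model is monotone in FIT, each p_t inverts to a FIT value
`(logit(p_t) − β₀)/β₁`; inversions outside the observed FIT range are
flagged extrapolated. The optimal band is the longest contiguous run of
grid points where the model strictly beats both references; an empty band
is a valid result, not an error.

## Monetary cost–benefit

The cost model prices the four triage outcomes: true positives save a
wasted capsule, true negatives avoid a colonoscopy, false positives pay
the colonoscopy/capsule price difference, and false negatives pay for a
capsule that converts. The capsule is priced at 83% of colonoscopy by
default (a published 17% differential); absolute tariffs are user
configuration because the original cost appendix is not public. For false
negatives both accountings are implemented: *incremental* (default) counts
only the wasted capsule, since the patient needed the colonoscopy under
either policy; *absolute* counts both procedures. Neither is presented as
the published analysis's certain intent. The curve is affine in each cost
component — asserted by finite differencing — so conclusions about *where*
the steep declines sit are invariant to the overall price level. Declines
are one-step drops on the grid, ranked, ties broken toward the lower
threshold.

## Sample size

The design calculation solves the noncentral-t power equation
(`stats::power.t.test`) for the continuous per-group n at Cohen's
d = delta/sd and reports the total as `ceiling(2n)`. Rounding the *total*
rather than each group is what yields an odd total (1441 at d = 20/117,
α = 0.05 two-sided, power 0.90, from n ≈ 720.2 per group); the per-group
ceiling convention (1442) and the normal approximation are reported
alongside. A nominal "effect size of 0.8" sometimes quoted alongside these
inputs is inconsistent with d = 20/117 ≈ 0.171 and is treated as a
misprint; the implementation derives d from delta and sd only.

# The synthetic cohort generator

The generator exists so every downstream stage is testable without patient
data. It states a world and keeps it fixed:

* **FIT**: log-normal with meanlog = log(16) and sdlog = 2.4. After
  upper-limit censoring at 400 µg/g this reproduces all three published
  marginal anchors simultaneously — median 16 µg/g, mean ≈ 78, SD ≈ 123 —
  and ≈ 60% of patients below 30 µg/g. The sdlog value is the root of the
  censored-mean equation at fixed median; because a single censored
  log-normal hits both moments, the two-component mixture contemplated as
  a fallback was unnecessary and is not implemented.
* **Assays**: each patient is measured on a lower-limit-7 or lower-limit-10
  assay (50/50 by default), and results are censored then re-imputed
  through the same parser the loader uses, so the generator's output is
  bit-identical to a round trip through CSV.
* **Outcome**: urgent ~ Bernoulli(logistic(β₀ + β₁·FIT)) on the *imputed*
  value, with defaults β₀ = −2.0, β₁ = 0.006 calibrated once to give
  urgent prevalence ≈ 0.20 (advanced polyps plus CRC plus polyp-burden
  conversions) and a FIT-vs-urgent AUC ≈ 0.69, matching the published
  discriminative performance for conversion.
* **Findings**: synthesised label-first — urgent cases receive CRC with
  probability 0.33, else an advanced polyp (80%) or a ≥ 3-polyp burden
  (20%); non-urgent cases receive only sub-threshold findings. This
  guarantees, by construction, that re-deriving the label from the
  findings reproduces the drawn label exactly; the generator asserts it
  and the suite re-checks it.
* **Covariates**: age ~ N(65.4, 14.3²) truncated at 18, 56.6% female,
  haemoglobin ~ N(112.2, 19.1²) g/L, bowel prep
  adequate/poor/missing = 0.419/0.026/0.555 — all drawn independently of
  FIT, because their joint distribution with FIT is unreported. Hooks for
  correlation would be additions to the stated world, not recalibrations.

What a green test on synthetic data establishes: the *machinery* is
correct — counts, scans, curves and fits agree with independent brute-force
oracles, and the generator's parameters are recoverable with nominal CI
coverage. What it does not establish: any clinical claim about real IDA
cohorts, whose FIT distribution, label prevalence and covariate
dependence will differ. Published cohort-specific results (specific AUC
values, jump-point lists, monetary figures) depend on an undeposited
dataset and unpublished tariffs and are deliberately not targets of the
test suite.

# Numerical conventions and edge cases

* Threshold comparisons are inclusive ("at or below"); imputed censored
  values participate exactly like exact values.
* The CUSUM grid, jump detection and rate lookups are integer arithmetic;
  `conversion_rate_at()` errors on off-grid thresholds and names the
  nearest grid point.
* Empty-set conventions: conversion rate is 0 when no patients are at or
  below t; a monotone non-decreasing monetary curve has no declines; an
  empty optimal band is returned as a zero-row tibble.
* Degenerate generator parameters (probabilities numerically constant)
  warn rather than error; degenerate model inputs (single-class outcome,
  zero-variance predictor, separation) error or flag loudly.
* Determinism: all generator randomness flows from one seed through
  `withr::with_seed` (no global RNG state leaks); a full pipeline run
  writes a JSON index that is byte-identical across runs with the same
  config and seed.

# Known limitations

* Conversion drivers other than pathology (incomplete capsule transit,
  poor bowel preparation) are out of scope; the label model is
  findings-only.
* The adjusted ROC is apparent performance; no cross-validation or
  optimism correction is provided.
* The monetary model is a per-patient accounting identity, not a health
  economic model: no QALYs, discounting or capacity dynamics.
* The referral criteria default is a documented stand-in, not a normative
  encoding of any national policy.
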