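---
title: "Methods: risk profiling, across-test variability and baseline volumetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk profiling, across-test variability and baseline volumetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurovar)
```

## What the package models

`neurovar` implements the baseline analysis of a healthy-aging cohort study
in which cardiovascular and cognitive risk burden, neuropsychological test
performance and structural brain measures are examined jointly. Three
quantities carry the analysis:

1. **Composite risk scores.** Five binary cardiovascular risk factors
   (diabetes, hypertension, dyslipidemia, active smoking, obesity) and two
   cognitive risk factors (depression risk, low education) are each worth
   one point. Every flag is an OR over clauses — a laboratory threshold, a
   self-report, a medication — so treated-and-controlled disease still
   counts as risk. The combined score (0–7) is the person's modifiable
   risk burden. APOE ε4 carriage is recorded but never scored: it is not
   modifiable.

2. **Intra-person across-test variability** $V_i$. Raw scores of a
   K = 14-subtest neuropsychological battery are z-transformed on the
   whole sample; for subject $i$ with z-scores $Z_{i,k}$ and mean
   $A_i = \frac1K\sum_k Z_{i,k}$,
   $$V_i = \sqrt{\frac{\sum_{k=1}^{K}(Z_{i,k}-A_i)^2}{K-1}},$$
   the sample standard deviation of the subject's own z-profile. In
   healthy, high-functioning samples most single tests saturate near
   ceiling; dispersion *across* domains remains informative and is the
   package's primary cognitive marker.

3. **TIV-normalised volumetrics.** All volumes are expressed as unitless
   fractions of total intracranial volume; white-matter lesions are
   aggregated from per-lesion records into a total fraction and
   periventricular / juxtacortical / deep-white class fractions, plus a
   lesion count. Fractions are multiplied by 100 only at the reporting
   layer.

Inference uses four tools: exhaustive predictor-subset OLS selected by
leave-one-out cross-validation, Spearman and partial (Pearson-on-residuals)
correlations, age-residualised median-split group comparisons with pooled
t-tests, and Holm step-down multiplicity correction.

## The battery definition

The battery ships as `default_battery()` and is user-overridable. The
14-subtest composition is: MMSE, Mattis, Corsi block-tapping (mean of the
direct- and inverse-span z-scores), digit span (likewise), Grober–Buschke
total recall, DMS immediate recall, Rey figure immediate and 3-minute
copies, Stroop interference time, TMT B−A, BREF, phonematic fluency,
semantic fluency and DO80. Two conventions needed a decision:

* **Orientation.** Timed scores (Stroop, TMT B−A) are negated *before*
  standardisation so that a higher oriented score always means better
  performance. $V_i$ is direction-sensitive only through orientation
  consistency, so this convention (and its override hook in the subtest
  specs) is what matters, not the sign itself.
* **TMT B−A** is computed as a raw time difference, matching the usual
  notation, not a ratio.
* **Missing subtests** are an error by default, listing the affected
  subjects. An explicit `missing = "available"` policy computes $V_i$ over
  the observed subtests with the denominator reduced accordingly and at
  least `min_k = 8` observed; `k_used` is reported so a changed
  denominator is always visible. Both the z-scoring and $V_i$ use the
  $n-1$ sample-SD convention.

## Risk-scoring decisions

* The blood-pressure clause reads "systolic ≥ 140 **or** diastolic ≥ 90"
  by default (`hypertension_rule = "or"`); the AND reading is available as
  an option. Self-report and medication clauses are unaffected.
* All thresholds are applied exactly as printed: glycemia > 1.26 g/L
  (strict), cholesterol > 2.5 mmol/L, BMI > 30, GDS > 9, amyloid
  positivity GCI > 1.45 — boundary values do not flag.
* Missing self-report/medication booleans are an error unless
  `assume_absent_when_missing = TRUE` is set explicitly: silently imputing
  "no risk" would bias scores downward invisibly.

## Model selection by LOOCV

`loocv_select(formula, data)` enumerates all $2^p-1$ nonempty subsets of
up to 12 candidate predictors. Each subset is scored by the
**bias-corrected LOOCV RMSE**: with leave-one-out residuals $e_i$, the
plain LOOCV RMSE is $\sqrt{\overline{e^2}}$ and the bias-corrected value
is $\sqrt{\overline{e^2}-\bar e^2}$ — the standard deviation of the
out-of-sample residuals, i.e. the RMSE with its mean-bias component
removed. Both are reported; selection uses the bias-corrected value. Ties
are broken toward the smaller subset, then lexicographically, so the
selection is invariant to candidate order. Leave-one-out residuals use the
exact OLS hat-matrix identity $e_i = r_i/(1-h_{ii})$; the test suite
asserts equality with an explicit n-refit loop to 1e-8. The selected
subset is refit on the full data for classical coefficient t-tests.

## Correlations, group comparisons, multiplicity

* Spearman correlations use mid-ranks (average ranks on ties) and the
  t approximation $t = r\sqrt{(n-2)/(1-r^2)}$, adequate at cohort-scale n;
  partial correlations are Pearson correlations of OLS residuals with
  $n-q-2$ df. A rank-based partial correlation is a noted variant, not the
  default.
* The median split of the combined risk score assigns ties at the median
  to the low group (`score <= median`), reproducing the "no or one risk
  factor" versus "more than one" partition when the median is 1. Age is
  regressed out of every compared outcome before the pooled
  (Student's) t-test; Welch's correction is available behind a flag.
* Holm families are declared explicitly per analysis block: the six
  temporal thickness comparisons (medial temporal, parahippocampal,
  entorhinal, both hemispheres) form one family; the $V_i$ and PET GCI
  comparisons are reported with their own labels. Raw and adjusted
  p-values are always emitted together.

## The synthetic cohort generator

No subject-level data are distributable, so `simulate_cohort()` generates
cohorts whose *marginals* match the published baseline summary (age
truncated-normal on [50, 70] around mean 60; 50% female; risk-flag
prevalences reproducing the printed score distributions; battery means/SDs;
tissue fractions 47.8/35.6/16.6% of TIV; negative-binomial lesion counts of
mean 10.6 with log-normal-like volumes split over the three classes;
a GCI mixture with 8.6% above the 1.45 positivity threshold) and whose
*cross-domain associations* are calibrated to the reported values: age vs
white-matter fraction r = −0.41, age vs lesion fraction r = 0.39, combined
risk vs $V_i$ partial r = 0.21 given age and gender, a 1.08-SD male–female
TIV gap, and reduced temporal thickness in the high-risk group.

The cognitive model is a single general factor $g_i$ plus subject-specific
noise: oriented subtest score $= \lambda g_i + s_i\,\varepsilon_{ik}$ with
$\log s_i = \mu + \beta\,(\text{combined risk})_c + \sigma u_i$. The scale
$s_i$ is the latent inconsistency and the recoverable ground truth behind
$V_i$; the risk coefficient $\beta$ induces the risk–variability
association. The loading is small ($\lambda = 0.3$) because the published
variability level itself implies it: with column-standardised scores, a
mean $V_i$ of 0.89 with SD 0.4 forces the across-test variance share close
to 1, i.e. nearly uncorrelated subtests — exactly the ceiling-dominated
regime the statistic was designed for. The three free parameters
$(\mu, \sigma, \beta)$ were calibrated once by a damped fixed-point search
at n = 40 000 against the targets (mean 0.89, SD 0.40, partial r 0.21) and
frozen at $\mu = 0.183$, $\sigma = 0.407$, $\beta = 0.1175$; they are
config entries, not data-dependent quantities.

Volumetric and lesion outcomes are linear in centred age, centred risk
scores, a standardised inconsistency driver and gender, with coefficients
derived in closed form from the target correlations and the analytic SD of
the truncated-normal age distribution, and residual noise filling the
variance budget; infeasible correlation budgets raise a configuration
error. One global seed expands into fixed per-table substreams, so adding
a table never perturbs the others, and `null_config()` zeroes every
cross-domain effect while keeping all marginals — the basis for the
pipeline's type-I-error checks.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: subtest scores are continuous (no integer
scoring, no hard ceilings beyond mild clipping), risk factors are drawn
independently rather than co-occurring, the within-battery correlation
structure is a single factor by assumption, lesion volumes have no spatial
structure, and there is no longitudinal dimension. The generator validates
the *pipeline*, not the cohort's biology.

Two marginal targets are knowingly approximate: an age SD of 6.3 is not
attainable for any distribution truncated to [50, 70] together with mean
60 and near-normal shape (the truncated-normal supremum is ≈ 5.8), so the
parent SD 7.9 yields a realised SD ≈ 5.6 and all age-linked slopes are
computed against the realised analytic SD; and the printed lesion-class
SDs exceed their means, which a Dirichlet class-share model reproduces
qualitatively (strong right skew) rather than exactly.

## Numerical choices and degenerate inputs

Zero-variance subtest columns, singular designs, constant correlation
inputs, zero pooled variance and all-identical median splits raise typed
errors naming the offending column or index rather than returning NaN.
Linear algebra is deterministic QR; the only randomness anywhere is in the
generator and in simulation-based tests, always behind explicit seeds.
Problem sizes used in the shipped checks — 10 000 subjects for calibration
checks, 200 replicates of n = 300 for selection power, 100 null cohorts of
n = 142 for family-wise error — were chosen to keep Monte-Carlo error
comfortably inside the assertion bands.

## Worked example

```{r example}
coh <- simulate_cohort(cohort_config(n = 142, seed = 42))
report <- run_baseline(coh)
report
```

## Limitations

Beyond the generator caveats above: the pipeline is baseline-only (the
PET–variability merge key degenerates to the baseline visit), no
mixed-effects or robust-SE variants are offered, family definitions for
the Holm correction are fixed per block rather than configurable per
analysis plan file, and the exhaustive search is deliberately capped at 12
candidates — beyond that, subset enumeration stops being an honest
reflection of how such models are compared.
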