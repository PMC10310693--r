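---
title: "Methods: MetS phenotyping, morphometry scans and PLS brain age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MetS phenotyping, morphometry scans and PLS brain age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsage)
```

This vignette is the package's account of its statistical machinery: the
models, their assumptions, the tunable parameters, the synthetic-data
generator, and the design decisions taken where the methodology left
genuine choices open.

## MetS severity

A participant's metabolic syndrome severity is the number of NCEP-ATP
III/IDF criteria met, an integer from 0 to 5:

* waist circumference ≥ 102 cm (males) / ≥ 88 cm (females);
* triglyceride ≥ 1.7 mmol/L, or lipid-lowering medication;
* HDL < 1.0 mmol/L (males) / < 1.3 mmol/L (females), or HDL medication;
* systolic BP ≥ 130 mmHg or diastolic ≥ 85 mmHg, or antihypertensives;
* HbA1c ≥ 42.0 mmol/mol, or glucose-lowering treatment.

All boundaries are inclusive exactly as written. Medication enters the
criterion as a three-valued OR, so a missing measurement is still decidable
when the medication flag is `TRUE`; a participant is *unevaluable* only
when neither the measurement nor a deciding medication flag is available,
and such rows are excluded and logged rather than imputed. HbA1c replaces
fasting glucose as the glycemia marker (a 2–3-month average, mmol/mol).

In the association models, hypertension enters as the binary criterion flag
rather than raw blood pressure: blood pressure is the one component that is
commonly summarised as a dichotomous status, and the raw systolic reading
is available via `hypertension = "sbp"` where a continuous predictor is
preferred. Whether triglyceride/HDL should be log-transformed before
regression is similarly left open by convention; the default is
untransformed raw values, which is what the scans report.

## Covariates

The default adjustment set is: age at the imaging visit, sex, Townsend
deprivation index, ethnicity (white / non-white), years of education,
smoking status (never / former / current), alcohol consumption frequency
(ordinal 0–5), employment status, brain size (total segmentation volume,
mm³) and imaging site. Handedness is available but excluded from the
default scheme; it matters only for lateralization checks. Education given
as qualification labels is mapped to years (degree 16; A/AS levels 13;
O levels/GCSE/CSE 11; NVQ/HND/HNC and other professional 10; never attended
0). Categorical covariates are dummy-coded against fixed reference levels
(female, white, never-smoker, working, Cheadle, right-handed) — the
reference choice affects parameterization only, not fits. Brain size is
included for all three measure kinds, thickness included, because the
adjustment list is defined once for the whole analysis rather than
per-kind.

## Unique-effect association scans

The five MetS components are substantially intercorrelated, so a plain
multiple regression spreads shared variance arbitrarily. The unique-effect
scan isolates one component in two steps: step 1 regresses each morphology
feature on the *other four* components (plus intercept) and keeps the
residuals; step 2 regresses those residuals on the component of interest
plus the covariates. Step 1 deliberately does **not** include the
covariates — it removes only the sibling components — and a
`step1_covariates = TRUE` toggle provides the sensitivity variant.

Two numerical notes. First, the step-2 degrees of freedom ignore step-1
estimation; the reported df is therefore mildly optimistic. The scan is a
screening device (its decisions are made on FDR-adjusted values), and the
full-model AIC mode below gives exact df where that matters. Second,
whenever the component of interest is orthogonal (in sample) to the other
four components and the covariates, the two-step coefficient equals the
full-model coefficient exactly — this identity is one of the package's
acceptance checks, at a relative tolerance of 1e-8 against an independent
normal-equations solver.

Multiple-testing correction is applied separately within each measure kind
(area, thickness, volume), mirroring the convention of reporting separate
statistical maps per kind. The default is Benjamini–Hochberg FDR at 0.01.
Random-field-theory cluster correction is out of scope here — it needs mesh
geometry and smoothness estimates that regional tables do not carry — so
the familywise alternative is a Freedman–Lane style maxT permutation test:
the predictor is residualized on the covariates, permuted, and each
feature's adjusted p-value is the add-one-corrected proportion of
permutations whose maximum |t| across the family reaches its observed |t|.
At least 100 permutations are required; the null familywise rejection rate
is verified by simulation to sit in the conservative band around the
nominal level. Ties in the BH step-up are resolved by stable ordering, so
output is deterministic.

## AIC winning-model maps

To ask which component best explains a feature, the five single-component
models are compared by the Gaussian-likelihood AIC computed from the
residual sum of squares, `n·ln(RSS/n) + 2(k+1)`, with the error variance
counted as a parameter and constants dropped (only differences are used).
The winner must beat the runner-up by **more than 2** AIC units; otherwise
the feature gets `none`. Exact ties give a delta of zero and hence no
winner — the conservative reading of the rule.

AIC comparison presumes a common dependent variable, but the literal
two-step procedure gives each component model a *different* residualized
outcome. The package therefore defaults to a full-model mode
(`feature ~ component + covariates`, five strictly comparable fits) and
offers the literal two-step variant behind `mode = "two_step"`; the
discrepancy is a property of the procedure, not of the implementation, and
is surfaced here rather than hidden.

## PLS brain age and the bias-corrected gap

Features significant for *any* component (union over the five scans) enter
a partial least squares regression of chronological age on the
standardized features. PLS is the right learner here: the features are
many, collinear and all weakly informative about age. The implementation
is SIMPLS with a univariate response; at full component count its
coefficients coincide with OLS, which the tests verify to 1e-6, and its
predictions are cross-checked against an independent PLS implementation
(`mixOmics`).

Cross-validation is 10-fold with uniformly random, seed-fixed fold
assignment (fold sizes differ by at most 1). Standardization statistics
are computed *inside* each training fold — never globally — which is what
makes the out-of-fold metrics honest; a pure-noise leakage guard
(out-of-fold |r| < 0.1 on noise features at n = 2000) is part of the
acceptance suite. The number of latent components is not prescribed by the
methodology, so the default selects it by an inner 5-fold CV minimizing
RMSE over 1..min(30, rank); a fixed `ncomp` skips the search. Reported r,
RMSE and MAE are out-of-fold; in-sample counterparts are also emitted for
comparison. Feature selection itself uses the full aging cohort, which
makes the CV metrics mildly optimistic; this matches the intended usage
(the model is deployed on *external* cohorts) and a caller wanting fully
nested evaluation can run `select_features` inside their own resampling
loop.

The raw brain-age gap (predicted minus chronological age) is biased by
regression to the mean: the model under-predicts old and over-predicts
young participants. The correction fits `gap ~ slope·age + intercept` on
the out-of-fold gaps of the aging cohort — slope *and* intercept, fitted
once, then **frozen** into the serialized model. Disease cohorts are scored
with the frozen line: re-fitting it per cohort would absorb exactly the
offset the analysis wants to measure. On the fitting cohort the corrected
gap is uncorrelated with age to numerical precision (< 1e-10, an
acceptance check). The model serializes to a single JSON document at 17
significant digits, which round-trips doubles exactly; predictions before
and after save/load are bit-identical.

## Group comparisons

Severity effects are assessed distributionally: two-sample KS contrasts of
the corrected gap between *adjacent* severity levels (0 vs 1, …, 4 vs 5;
all-pairs available), BH-FDR at 0.05 across the performed contrasts. The
KS p-value uses the asymptotic two-sample Kolmogorov distribution by
default; the exact computation is offered for small groups (min n < 30).
Disease cohorts are contrasted against the aging cohort the same way.

Propensity matching uses logistic regression on the covariate design,
greedy 1:1 nearest-neighbour matching on the logit propensity without
replacement, in descending order of treated propensity, with a default
caliper of 0.2 SD of the logit propensity. Greedy matching is not optimal
matching, but it is transparent and deterministic, and the standardized
mean differences before/after (emitted by `match_balance()`) make any
residual imbalance visible instead of assumed away. Matched comparisons use
the pooled-variance two-sample t-test by default (paired via flag).

## The synthetic-data generator

The generator is a first-class module, not a fixture: it defines the study
conditions under which every downstream claim is tested. It emulates a
population-based aging cohort — the real counterpart of such data is
access-restricted — with:

* ages uniform on (47, 79) years; sex 46.3% male;
* the five MetS measurements from a Gaussian copula (default correlation
  0.3 between pairs, 0.45 waist–triglyceride, −0.45 triglyceride–HDL, and
  mildly negative HDL pairings) mapped to Gaussian marginals centred at
  realistic population moments (waist 87.4 ± 12.4 cm, triglyceride
  1.62 ± 0.94 mmol/L, HDL 1.49 ± 0.37 mmol/L, SBP 138 ± 18 mmHg, HbA1c
  34.8 ± 4.95 mmol/mol) and truncated at physiologic floors. SBP/DBP
  population moments are not tabulated alongside the others and are chosen
  as realistic stand-ins;
* medication flags as independent Bernoulli draws (lipid 0.15, BP 0.21,
  glucose 0.05), which puts the severity distribution's mean near 1.4;
* morphology features equal to a kind-level baseline plus a per-feature
  age slope times centred age, plus planted component effects, plus
  Gaussian noise; thickness is clipped positive. Age slopes default to
  −2 mm²/y (area), −0.004 mm/y (thickness) and −15 mm³/y (volume) with
  ±40% per-feature variation, against noise SDs of 60 mm², 0.08 mm and
  250 mm³ — per-feature age correlations of roughly 0.3–0.6, so that ~90
  features jointly support accurate age prediction. Planted MetS effects
  follow the direction convention *worse MetS → larger area, thinner
  cortex, smaller subcortical volume* and are expressed in noise-SD units
  per SD of component burden (HDL's burden is its negated z-score);
  obesity (waist) carries 1.5× the effect of the other components;
* disease cohorts generated at an *effective age* of chronological age
  plus a planted offset, so a correct brain-age model should recover the
  offset as the mean corrected gap. The default offsets (stroke 0.47,
  Parkinson's 1.28, multiple sclerosis 1.94, dementia 2.44 years) encode
  the expected clinical ordering.

Everything planted is returned as ground truth, and regeneration under the
same config and seed is bit-identical; stage-level substreams derived from
the one global seed keep the draws of different stages decoupled.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: spatial autocorrelation between neighbouring
regions, scanner/site batch effects beyond a categorical covariate,
non-Gaussian (skewed) biomarker marginals, measurement error in the MetS
components, non-linear age trajectories, and selection effects of cohort
recruitment. The generator's distributional choices are stand-ins, stated
here so they are not mistaken for empirical claims.

## Problem sizes and tolerances

The test suite runs the exact-identity checks (OLS oracle, two-step/full
agreement, KS brute force, round-trip serialization) at small n where the
tolerances are 1e-6 to 1e-12, and the statistical-calibration checks at
the sizes a desk-scale study of each property needs: FDR nulls at 500
replicates of 1000 features × 200 participants; maxT familywise error at
200 replicates of 500 permutations; winner-map recovery and the PLS
leakage guard at n = 2000; severity ordering at n = 5000; disease-offset
recovery at 20 seeds of n = 1000. These sizes were chosen so each check is
statistically informative while the whole suite stays comfortably fast.
Degenerate inputs are rejected rather than patched: perfect fits have no
Gaussian AIC, constant predictors and rank-deficient designs abort with
the offending columns named, and empty feature selections raise guidance
instead of an empty model.
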