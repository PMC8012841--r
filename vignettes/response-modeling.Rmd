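---
title: "Historical-control response modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Historical-control response modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsresponder)
```

This vignette is the package's own account of the statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The analysis arc

A small treated ALS cohort is evaluated against a large historical-control
population in five stages.

1. **Group-level survival.** Kaplan–Meier curves with log-log Greenwood
   intervals, log-rank and generalized-Wilcoxon (Gehan) tests, an adjusted
   Cox model (Efron ties), a fully parametric exponential model (the same
   linear predictor under full maximum likelihood, which also accommodates
   product interaction terms such as group × age), and a Weibull accelerated
   failure time model whose `exp(coefficient)` is the event-time ratio (ETR)
   of a covariate. Treated-versus-control effects are reported in both
   directions, explicitly labelled, since the field quotes both.
2. **Matched pairs.** Each treated patient receives its k = 10 nearest
   controls by Mahalanobis distance on age and baseline ALSFRS-R
   (standardized against the control pool), assigned greedily without
   replacement in a seeded random treated order. Matching quality is
   checked by TOST equivalence at a margin of 0.5 pooled SD. Each bootstrap
   draw then samples 9 of the 10 controls per treated patient, computes
   per-arm Kaplan–Meier medians and a Yang–Zhou (YP) short-/long-term
   hazard-ratio test; aggregates are reported as the mean of the per-draw
   medians and the median and range of the p-values.
3. **Functional decline.** A linear mixed model of ALSFRS-R on group, month
   (restricted cubic spline, three knots), the group × month interaction and
   baseline covariates, with a per-patient random intercept and slope; a
   three-way extension adds group × month × latency.
4. **Responder classification.** The core model: survival of *deceased*
   controls is exponential with reciprocal link,
   `mu = 1/(b0 + b1*slope + b2*age + b3*latency)`. Treated patients are
   classified by the residual `observed − mu` against a ±60-day band.
5. **Biomarker signature.** Baseline-anchored trapezoidal areas for each
   cytokine over months 3–9; per-package non-linear PCA; PC-score group
   tests; a meta-PC built from the significant PCs; ROC with a label-
   permutation p-value, per analysis window (3, 6, 12 months).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `responder_band` | 60 | days | The "negligible difference" band. Two months is small against a ~13-month median survival but large against visit-schedule granularity; `sensitivity_sweep()` exposes it, and the non-assignable count is monotone in it by construction. |
| slope window | 3 | months | Early-treatment visits only, so the predictor is available at the decision point; also used for controls for symmetry. |
| `k`, `subsample` | 10, 9 | patients | Matched-set size and the 9-of-10 per-draw subsample. |
| TOST margin | 0.5 | pooled SD | A conventional moderate equivalence margin; no narrower margin is identifiable at n = 36 per arm. |
| `loading_cutoff` | 0.5 | — | Absolute loading threshold for naming a component; read strictly ("over 0.5"). |
| `alpha` | 0.05 | — | PC selection into the meta-PC and all significance flags. |
| decline window | 6 | months | The primary early-treatment analysis window; configurable. |

## What the generator emulates — and what it does not

`cohort_spec()` defaults describe a riluzole/placebo historical-control arm
(age 58.4 ± 11 y, 39.4% female, baseline ALSFRS-R 36.9, onset-to-treatment
latency 557 days, median survival 398 days from treatment start) and
`treated_spec()` a 36-patient treated cohort (age 51.9, ALSFRS-R 37.6,
latency 595 days, 30.6% female, 8/36 bulbar). Survival is exponential with a
log-linear hazard in the covariates; the per-covariate coefficients are
simulation parameters chosen for plausibility (hazard increasing in age,
bulbar onset and latency, decreasing in baseline function), not estimates
from any dataset, and the baseline hazard is calibrated so the mean-covariate
patient hits the target median. Censoring is administrative at a fixed
horizon (1,500 days for controls, 2,400 for the treated cohort — long enough
that most control deaths are observed, finite enough that censoring paths are
exercised). A latent responder flag (probability 15/36 at the mean age,
log-odds decreasing 0.06/year so younger patients respond more often)
multiplies the event time by 2.5, attenuates the ALSFRS-R slope by the factor
0.4, and shifts one factor per biomarker package by 1.5 SD — downward for the
inflammatory cytokine factor, upward for stem-cell mobilisation and for the
motor-system fractional-anisotropy factor. Responder biomarker shifts begin
*after* baseline: they are treatment effects, and a baseline shift would
cancel out of the baseline-anchored areas. Imaging panels exist only at the
late timepoint, so early windows exercise the absent-package path.

Deliberately not emulated: correlation between the ALSFRS-R slope and
survival (the generator draws them independently given the covariates, so
the fitted slope coefficient is genuinely near zero — real data would give
the slope most of the predictive weight); plateau dynamics of late ALSFRS-R
trajectories; informative censoring or dropout; any covariate joint
distribution beyond independent marginals; imaging or flow-cytometry raw
data (per-ROI and per-count tables are the inputs). Passing tests therefore
demonstrate that the *procedures* recover structure they were given, not
that real ALS data contain that structure.

Two consequences of the exponential survival law deserve emphasis, because
they bound what responder-label recovery can achieve on this synthetic world:

* Given the covariates, an exponential time has coefficient of variation 1.
  With mean control survival around 574 days and a ±60-day band, the closed
  form gives a non-responder a probability of about 0.59 of being labelled
  correctly but 0.33 of out-living the band by chance; responders (2.5-fold
  multiplier) are labelled correctly with probability about 0.64. Among
  assignable patients the expected accuracy is therefore in the mid-60s of
  percent — an information-theoretic ceiling of the scenario, not a defect
  of the classifier. The recovery checks in the test suite measure exactly
  this level. A `weibull_shape` parameter (> 1 reduces the dispersion) is
  exposed for experiments that need a stronger latent signal.
* Training on deceased patients only — the procedure's definition — under
  administrative censoring truncates the outcome distribution, so
  predictions are biased low (E[T | T < W] < E[T]), and the bias grows as
  the censoring horizon shrinks. The package follows the procedure and does
  not correct this; the self-training calibration check uses an uncensored
  cohort, where the mean residual is near zero.

## Numerical choices

* **Reciprocal-link exponential fit** (`expsurv()`): Newton–Raphson on the
  exact log-likelihood `sum(log(x'b) - t * x'b)`, which is concave on the
  feasible region `x'b > 0`. Start from least squares of `1/t` on the
  covariates, shrunk toward the intercept-only solution until feasible;
  step-halving keeps iterates feasible; convergence at relative
  log-likelihood change `< 1e-8`, followed by one polishing Newton step
  (quadratic convergence squares the residual error, making closed-form
  cases exact to machine precision). Covariates are standardized internally
  and coefficients reported on the original day⁻¹ scale. Nonpositive
  predictors at prediction time flag the patient `unpredictable` rather than
  failing globally.
* **Weighted log-rank**: computed directly with hypergeometric covariance;
  the Wilcoxon variant uses at-risk-count (Gehan) weights.
* **YP model**: point estimates maximize a pseudo partial likelihood with
  the pooled left-continuous Kaplan–Meier plugged in for the baseline
  survival; the hazard-ratio function interpolates `exp(b1)` (short term) to
  `exp(b2)` (long term). The joint test of both ratios equal to 1 is a 2-df
  score test whose components are weighted log-rank statistics with
  predictable weights `S(t−)` and `1 − S(t−)` — this keeps the null
  calibration exact in distribution, which a Wald test with a plugged-in
  baseline would not. Below 30 subjects per arm the p-value switches to a
  label-permutation version of the same statistic.
* **Restricted cubic spline**: truncated-power natural spline, knots at the
  10th/50th/90th percentiles of observed months, linear beyond the boundary
  knots.
* **Mixed models**: REML via `lme4`/`lmerTest` (Satterthwaite tests); a
  singular random-intercept-and-slope fit falls back automatically to a
  random intercept, flagged in the result.
* **NLPCA**: alternating least squares on the standardized matrix — SVD,
  re-imputation of missing entries from the current low-rank reconstruction,
  monotone re-quantification of ordinal variables by weighted
  pool-adjacent-violators against the reconstruction, re-standardization —
  until the observed-entry reconstruction error changes by `< 1e-6` (at most
  500 cycles). On complete scalar data this reduces to classical PCA of the
  correlation matrix after a single cycle. Component signs are fixed by
  orienting each component's largest-|loading| variable positive; loadings
  are variable–score correlations; scores are normalized to mean 0, SD 1.
* **Meta-PC**: first principal component of the standardized
  patient × significant-PC score matrix (missing scores mean-imputed with a
  logged count), sign-oriented so responders score higher. **ROC**: AUC by
  the rank (Mann–Whitney) formulation; significance by seeded label
  permutation, one-sided.
* **Ties**: Efron's method in the Cox model (daily-resolution times make
  ties likely); waterfall ordering breaks residual ties by patient id.
* **Reproducibility**: every stochastic routine takes a seed and restores
  the caller's RNG state; the pipeline derives per-stage seeds from one
  master seed so stages can be re-run in isolation, and the run manifest
  records an md5 hash per artifact.

## Design choices that were genuinely open

* "Robust estimate" of the ALSFRS-R slope is implemented as Theil–Sen
  (median of pairwise slopes), with OLS as a config alternative; fewer than
  two distinct visit times yields an `NA` marker, never an error, so the
  patient survives into downstream tables as unpredictable.
* Censored treated patients can be classified *responder* (they already
  outlived prediction by more than the band) but never *non-responder* (a
  shortfall cannot be proven under censoring); they are otherwise
  non-assignable. This asymmetry is the package's construction.
* PC selection for the meta-PC uses the significance rule (every PC whose
  group test passes at `alpha`), not the highest-variance rule; both views
  are reported in the PC-test table (`vaf` column), since a highest-VAF
  selection is also defensible and the two disagree precisely when the
  response-linked factor is not the dominant source of variance.
* The matched-pair comparison matches on age and baseline ALSFRS-R;
  whether matching should consume controls with or without replacement is
  unsettled, and the greedy without-replacement choice (randomized order,
  re-randomized per seed) guarantees distinct controls within and across
  sets at the cost of slight order dependence.
* The group test behind the cytokine-area panel is the rank-sum test
  (Welch t as an option), with the conventional p < 0.1 reporting flag for
  that panel and `alpha` everywhere else.
* Internal time unit is days; months enter as days/30.44.

## Problem sizes used by the test suite

The acceptance checks run at the sizes the analyses are designed for:
20,000 draws for closed-form Kaplan–Meier agreement, 1,000 null simulations
for log-rank size, 100 repetitions at n = 2,000 for GLM coverage, 50
repetitions of the 2,000-control / 36-treated recovery scenario, 500
bootstrap draws at 36 treated for the matched-pair alternative, 3,000 per
arm for YP recovery under proportional hazards, 200 repetitions at
36 + 500 patients for decline-model power, and 50 repetitions of the
36-patient signature scenario. The matched-pair bootstrap defaults to 500
draws in the pipeline configuration; the aggregate stabilizes well below
that (doubling draws moves the mean-of-medians by under 1%), and the draw
count is a config value for users who want more.

## Known limitations

* Accuracy of responder recovery on the default synthetic world is ceiling-
  limited by the exponential noise (see above); comparisons of classifier
  variants on this generator mostly measure that ceiling.
* The YP pseudo-likelihood point estimates ignore the sampling error of the
  plugged-in baseline; their dispersion at a few hundred events per arm is
  appreciable (the long-term ratio especially), which is why recovery
  checks run at thousands of events.
* The NLPCA imputation assumes entries are missing completely at random,
  matching the generator; informative missingness would bias loadings.
* `fit_decline` fits a single residual variance across groups and months;
  floor effects of the score near 0 and 48 are handled only by clipping in
  the generator, not by the model.
* No multiplicity correction is applied across biomarker panels or windows
  beyond the dimension reduction itself — the design's stated rationale for
  using PC scores in the first place.
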