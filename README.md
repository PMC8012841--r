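# alsresponder

Inference of individual treatment response in amyotrophic lateral sclerosis
(ALS) cohorts followed against a historical control database.

ALS trials are small and survival is heterogeneous, so a drug's effect is easy
to miss at the group level even when a subset of patients benefits strongly.
`alsresponder` implements an analysis arc for exactly that situation: a small
treated cohort (say, 36 patients on a hematopoietic growth factor) is compared
against a large historical control population, a survival model trained on
deceased controls assigns each treated patient an *expected* survival, and the
sign and size of the observed-minus-predicted residual classifies the patient
as responder, non-responder, or non-assignable. Multimodal biomarker panels
(serum cytokines, hematology and stem-cell mobilisation counts, DTI
fractional-anisotropy regions) are then tested for whether they predict that
response within the first months of therapy.

Because the reference databases that motivate this design are
access-restricted, the package ships a synthetic-cohort generator that
reproduces their table shapes and statistical structure (covariates,
exponential survival with log-linear hazards, administrative censoring,
longitudinal ALSFRS-R decline with a latent responder effect, factor-model
biomarker panels with ordinal variables and missing entries). Every stage of
the pipeline is therefore runnable and testable without any download.

## The model at the core

Survival times of deceased historical controls are modelled as exponential
with a reciprocal link:

    T_i ~ Exponential(mean mu_i),    mu_i = 1 / (x_i' beta),

with covariates x_i = (1, ALSFRS-R slope, age, treatment latency). The ALSFRS-R
slope is a Theil–Sen estimate over the early visit window. Applied to a
treated patient, the model yields a predicted survival mu_i; with residual
r_i = observed_i − mu_i and a non-assignable band of ±delta days (default 60):

* `responder` if r_i > +delta (censored patients included — they have already
  outlived their prediction),
* `non-responder` if r_i < −delta and death was observed,
* `non-assignable` otherwise (in particular censored patients short of the
  band, whose shortfall censoring makes unprovable).

Around this core the package provides Kaplan–Meier/log-rank/Cox/parametric/AFT
survival comparisons, a matched-pair bootstrap (k nearest controls per treated
patient, 9-of-k resampling, Yang–Zhou short-/long-term hazard-ratio test),
mixed-effects restricted-cubic-spline models of ALSFRS-R decline, and the
biomarker signature stage (baseline-anchored cytokine areas, non-linear PCA
with optimal scaling, meta-PC, permutation-tested ROC).

## Worked example

```r
library(alsresponder)

ctrl   <- generate_control_cohort(cohort_spec(n_patients = 2000, seed = 1))
visits <- generate_trajectories(ctrl, trajectory_spec(), seed = 2)
model  <- fit_survival_glm(ctrl, slope_table(visits, max_month = 3))
summary(model)
#> Exponential survival regression (reciprocal link)
#>   n = 1717, log-likelihood = -12246.16
#>                 Estimate  Std. Error z value  Pr(>|z|)
#> (Intercept)   5.7319e-04  2.8429e-04  2.0162   0.04378 *
#> slope        -6.4177e-05  5.0974e-05 -1.2590   0.20802
#> age           2.3849e-05  4.5544e-06  5.2364 1.637e-07 ***
#> latency_days  2.6512e-07  1.8236e-07  1.4538   0.14601
```

The model trains on the 1,717 deceased controls with a defined early slope;
coefficients are on the reciprocal-mean scale (day⁻¹ per covariate unit), so
the positive age coefficient means older patients have shorter expected
survival. Applying it to a synthetic treated cohort and classifying:

```r
trt    <- generate_treated_cohort(treated_spec())
tv     <- generate_trajectories(trt$patients, trajectory_spec(), trt$latent, seed = 3)
pred   <- predict_survival(model, trt$patients, slope_table(tv, max_month = 3))
labels <- classify_response(trt$patients$survival_days, !trt$patients$event,
                            pred$predicted_days, threshold = 60,
                            patient_id = trt$patients$patient_id)
table(labels$label)
#>      responder  non-responder non-assignable
#>             21             13              1

contrast <- response_survival_contrast(labels)
contrast$medians
#>     responder non-responder
#>     1374.0251      133.1105
contrast$test
#> Log-rank test: chisq = 44.745 on 1 df, p = 2.245e-11
```

One patient died before a slope could be estimated and is unpredictable (`NA`
label). Model-identified responders have a median survival of 1,374 days
against 133 days for non-responders — the latent 2.5-fold event-time
multiplier the generator planted, amplified by the classification itself
(labels partly select on observed survival, so this contrast describes the
labels, not a causal effect).

The whole arc — simulation, survival comparisons, matching and bootstrap,
decline models, responder classification, biomarker signature — runs as one
pipeline:

```r
cfg <- run_config(seed = 123)
run_pipeline(cfg, "out")          # writes delimited artifacts + manifest.json
sensitivity_sweep(cfg, list(thresholds.responder_band = c(30, 60, 90)))
```

A thin command-line wrapper with the same subcommands lives at
`inst/scripts/als_pipeline.R`.

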