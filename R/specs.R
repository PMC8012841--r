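# Specification objects for the synthetic cohort generators. Defaults emulate
# the baseline characteristics of a riluzole/placebo historical-control arm and
# a 36-patient treated cohort (age, ALSFRS-R, onset-to-treatment latency, sex
# and onset-site mix, median survival about 13 months from treatment start).

#' Cohort specification for the synthetic historical-control generator
#'
#' Describes the joint distribution of covariates and survival for one cohort.
#' Survival is drawn from an exponential law whose per-patient rate is
#' `baseline_hazard * exp(x . log_hazard_betas)`, with administrative censoring
#' at `censor_window` days. A Weibull shape parameter is exposed as an optional
#' extension (`weibull_shape = 1` recovers the exponential default); the time
#' multiplier is applied on the time scale so covariate effects stay
#' log-linear in the hazard.
#'
#' @param n_patients number of patients.
#' @param age_mean,age_sd age at treatment start, years.
#' @param frac_female,frac_bulbar proportions in \[0, 1\].
#' @param baseline_alsfrs_mean,baseline_alsfrs_sd baseline ALSFRS-R score
#'   points; draws are rounded and clipped to \[0, 48\].
#' @param latency_mean,latency_sd onset-to-treatment latency, days.
#' @param riluzole_prob probability of riluzole use.
#' @param baseline_hazard events/day for a patient at the covariate values
#'   named in `log_hazard_betas`' centering attribute. When `NULL` (default) it
#'   is set so that a patient at the cohort's mean covariates has median
#'   survival `target_median_days`.
#' @param log_hazard_betas named per-covariate log-hazard coefficients; names
#'   must be a subset of `age`, `female`, `bulbar`, `baseline_alsfrs`,
#'   `latency_days`, `riluzole`.
#' @param target_median_days median survival (days) of the mean-covariate
#'   patient, used only when `baseline_hazard` is `NULL`.
#' @param censor_window administrative censoring horizon, days (`Inf` allowed).
#' @param weibull_shape Weibull shape parameter; 1 = exponential (default).
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 2000L,
                        age_mean = 58.4, age_sd = 11,
                        frac_female = 0.394,
                        frac_bulbar = 0.30,
                        baseline_alsfrs_mean = 36.9, baseline_alsfrs_sd = 5.4,
                        latency_mean = 557, latency_sd = 290,
                        riluzole_prob = 1,
                        baseline_hazard = NULL,
                        log_hazard_betas = c(age = 0.025, female = -0.10,
                                             bulbar = 0.35,
                                             baseline_alsfrs = -0.05,
                                             latency_days = 2e-4,
                                             riluzole = -0.05),
                        target_median_days = 398,
                        censor_window = 1500,
                        weibull_shape = 1,
                        seed = 1L) {
  check_count(n_patients, "n_patients")
  check_prob(frac_female, "frac_female")
  check_prob(frac_bulbar, "frac_bulbar")
  check_prob(riluzole_prob, "riluzole_prob")
  check_pos(age_sd, "age_sd", strict = FALSE)
  check_pos(baseline_alsfrs_sd, "baseline_alsfrs_sd", strict = FALSE)
  check_pos(latency_sd, "latency_sd", strict = FALSE)
  check_pos(censor_window, "censor_window")
  check_pos(weibull_shape, "weibull_shape")
  if (baseline_alsfrs_mean < 0 || baseline_alsfrs_mean > 48) {
    stop("invalid `baseline_alsfrs_mean`: must be in [0, 48]", call. = FALSE)
  }
  allowed <- c("age", "female", "bulbar", "baseline_alsfrs", "latency_days", "riluzole")
  if (length(log_hazard_betas) &&
      (is.null(names(log_hazard_betas)) || !all(names(log_hazard_betas) %in% allowed))) {
    stop("invalid `log_hazard_betas`: names must be among ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  typical <- c(age = age_mean, female = frac_female, bulbar = frac_bulbar,
               baseline_alsfrs = baseline_alsfrs_mean, latency_days = latency_mean,
               riluzole = riluzole_prob)
  if (is.null(baseline_hazard)) {
    check_pos(target_median_days, "target_median_days")
    lp_typ <- if (length(log_hazard_betas)) {
      sum(log_hazard_betas * typical[names(log_hazard_betas)])
    } else 0
    baseline_hazard <- log(2)^(1 / weibull_shape) / target_median_days * exp(-lp_typ)
  }
  check_pos(baseline_hazard, "baseline_hazard")
  structure(list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd,
    frac_female = frac_female, frac_bulbar = frac_bulbar,
    baseline_alsfrs_mean = baseline_alsfrs_mean,
    baseline_alsfrs_sd = baseline_alsfrs_sd,
    latency_mean = latency_mean, latency_sd = latency_sd,
    riluzole_prob = riluzole_prob,
    baseline_hazard = baseline_hazard,
    log_hazard_betas = log_hazard_betas,
    censor_window = censor_window,
    weibull_shape = weibull_shape,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Treated-cohort specification
#'
#' Extends a [cohort_spec()] with a latent responder structure: each patient is
#' a responder with probability `plogis(qlogis(responder_fraction) +
#' age_interaction * (age - age_mean))`, and responder event times are
#' multiplied by `responder_etr` before censoring.
#'
#' @param base a [cohort_spec()]; defaults describe a 36-patient treated cohort.
#' @param responder_fraction expected responder proportion at the mean age.
#' @param responder_etr event-time multiplier for responders (> 1 prolongs).
#' @param age_interaction per-year additive effect (log-odds scale) of age on
#'   responder probability; negative values favour younger patients.
#' @return an object of class `treated_spec`.
#' @export
treated_spec <- function(base = cohort_spec(n_patients = 36L,
                                            age_mean = 51.9, age_sd = 10.5,
                                            frac_female = 0.306,
                                            frac_bulbar = 8 / 36,
                                            baseline_alsfrs_mean = 37.6,
                                            baseline_alsfrs_sd = 5.7,
                                            latency_mean = 595, latency_sd = 350,
                                            riluzole_prob = 1,
                                            censor_window = 2400,
                                            seed = 2L),
                         responder_fraction = 15 / 36,
                         responder_etr = 2.5,
                         age_interaction = -0.06) {
  if (!inherits(base, "cohort_spec")) stop("invalid `base`: must be a cohort_spec", call. = FALSE)
  check_prob(responder_fraction, "responder_fraction")
  check_pos(responder_etr, "responder_etr")
  if (!is.numeric(age_interaction) || length(age_interaction) != 1L || is.na(age_interaction)) {
    stop("invalid `age_interaction`: must be a single number", call. = FALSE)
  }
  structure(list(base = base,
                 responder_fraction = responder_fraction,
                 responder_etr = responder_etr,
                 age_interaction = age_interaction),
            class = "treated_spec")
}

#' Longitudinal ALSFRS-R trajectory specification
#'
#' Scores follow `clip(baseline + slope * month + noise, floor, 48)` at the
#' scheduled visit months that fall strictly before death or censoring.
#' Responder slopes are multiplied by `responder_slope_attenuation`.
#'
#' @param visit_months strictly increasing visit schedule in months, first 0.
#' @param slope_mean,slope_sd per-patient slope distribution, points/month
#'   (negative mean = decline).
#' @param floor lower plateau of the score, points in \[0, 48\].
#' @param noise_sd visit-level measurement noise, points.
#' @param responder_slope_attenuation multiplier in (0, 1\] applied to
#'   responder slopes (smaller = flatter decline).
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(visit_months = 0:12,
                            slope_mean = -1.0, slope_sd = 0.5,
                            floor = 0, noise_sd = 1.5,
                            responder_slope_attenuation = 0.4) {
  if (length(visit_months) < 1L) {
    stop("invalid `visit_months`: must contain at least one visit", call. = FALSE)
  }
  if (visit_months[1] != 0 || is.unsorted(visit_months, strictly = TRUE)) {
    stop("invalid `visit_months`: must be strictly increasing with first = 0",
         call. = FALSE)
  }
  if (floor < 0 || floor > 48) stop("invalid `floor`: must be in [0, 48]", call. = FALSE)
  check_pos(slope_sd, "slope_sd", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (responder_slope_attenuation <= 0 || responder_slope_attenuation > 1) {
    stop("invalid `responder_slope_attenuation`: must be in (0, 1]", call. = FALSE)
  }
  structure(list(visit_months = as.numeric(visit_months),
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 floor = floor, noise_sd = noise_sd,
                 responder_slope_attenuation = responder_slope_attenuation),
            class = "trajectory_spec")
}

#' Biomarker panel specification
#'
#' A linear factor model per timepoint: values are
#' `loading_matrix %*% (factor scores + responder_effect * flag) + noise`,
#' with patient-level persistence of factor scores across timepoints, quantile
#' discretisation of ordinal variables and completely-at-random missingness.
#'
#' @param loading_matrix numeric variable-by-factor matrix with rownames
#'   (variable names); every row must have at least one non-zero entry.
#' @param responder_effect per-factor mean shift applied to responders.
#' @param ordinal_vars named integer vector: variables to discretise and their
#'   bin counts (each >= 2).
#' @param missing_rate completely-at-random missingness proportion in \[0, 1).
#' @param timepoints months at which panels are produced.
#' @param noise_sd sd of the variable-level noise.
#' @param within_patient_cor correlation of a variable's factor score across
#'   timepoints of one patient.
#' @param seed integer RNG seed.
#' @return an object of class `biomarker_spec`.
#' @export
biomarker_spec <- function(loading_matrix,
                           responder_effect = rep(0, ncol(loading_matrix)),
                           ordinal_vars = integer(),
                           missing_rate = 0.1,
                           timepoints = c(0, 3, 6, 9, 12),
                           noise_sd = 0.6,
                           within_patient_cor = 0.7,
                           seed = 3L) {
  loading_matrix <- as.matrix(loading_matrix)
  if (is.null(rownames(loading_matrix))) {
    rownames(loading_matrix) <- paste0("var", seq_len(nrow(loading_matrix)))
  }
  if (any(rowSums(abs(loading_matrix)) == 0)) {
    bad <- rownames(loading_matrix)[rowSums(abs(loading_matrix)) == 0][1]
    stop(sprintf("invalid `loading_matrix`: variable '%s' has all-zero loadings (unidentifiable)", bad),
         call. = FALSE)
  }
  if (any(colSums(abs(loading_matrix)) == 0)) {
    stop("invalid `loading_matrix`: every factor needs at least one variable", call. = FALSE)
  }
  check_prob(missing_rate, "missing_rate", open_right = TRUE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_prob(within_patient_cor, "within_patient_cor")
  if (length(responder_effect) != ncol(loading_matrix)) {
    stop("invalid `responder_effect`: one value per factor required", call. = FALSE)
  }
  if (length(ordinal_vars)) {
    if (is.null(names(ordinal_vars)) || !all(names(ordinal_vars) %in% rownames(loading_matrix))) {
      stop("invalid `ordinal_vars`: names must match loading_matrix variables", call. = FALSE)
    }
    if (any(ordinal_vars < 2)) {
      stop("invalid `ordinal_vars`: every ordinal bin count must be >= 2", call. = FALSE)
    }
  }
  structure(list(n_factors = ncol(loading_matrix),
                 loading_matrix = loading_matrix,
                 responder_effect = as.numeric(responder_effect),
                 ordinal_vars = ordinal_vars,
                 missing_rate = missing_rate,
                 timepoints = as.numeric(timepoints),
                 noise_sd = noise_sd,
                 within_patient_cor = within_patient_cor,
                 seed = as.integer(seed)),
            class = "biomarker_spec")
}

#' Default multimodal biomarker packages
#'
#' Three panels mirroring the multimodal setting: serum cytokines/growth
#' factors (inflammatory factor shifted down in responders), hematology and
#' stem-cell mobilisation counts (mobilisation factor shifted up in
#' responders, two ordinal grading variables), and DTI fractional-anisotropy
#' regions of interest (motor-system factor shifted up in responders,
#' available only at the late timepoint, as imaging follow-up usually is).
#'
#' @param responder_sd_shift absolute factor-score shift (in sd units) between
#'   responders and non-responders on each package's response-linked factor.
#' @return named list of three [biomarker_spec()] objects
#'   (`cytokines`, `hematology`, `imaging`).
#' @export
default_biomarker_specs <- function(responder_sd_shift = 1.5) {
  cyto_vars <- c("IL6", "MCP1", "eotaxin", "MCP4", "TNFb", "IL7",
                 "IL8", "IL10", "TNFa", "IFNg", "VEGF", "IL2")
  cyto_load <- matrix(0, length(cyto_vars), 3, dimnames = list(cyto_vars, NULL))
  cyto_load[1:6, 1] <- 0.8                      # inflammatory axis
  cyto_load[7:10, 2] <- 0.75                    # regulatory axis
  cyto_load[11:12, 3] <- 0.7                    # trophic axis
  cyto_load[7, 1] <- 0.3
  hema_vars <- c("CD34pos", "CD34posCD38neg", "WBC", "monocytes", "neutrophils",
                 "lymphocytes", "platelets", "hemoglobin", "mobilization_grade",
                 "tolerability_grade")
  hema_load <- matrix(0, length(hema_vars), 3, dimnames = list(hema_vars, NULL))
  hema_load[c(1, 2, 4, 9), 1] <- 0.85           # stem-cell mobilisation axis
  hema_load[c(3, 5, 6), 2] <- 0.8               # leukocyte axis
  hema_load[c(7, 8, 10), 3] <- 0.7
  img_vars <- c(paste0("FA_motor_", 1:6), paste0("FA_frontal_", 1:5),
                paste0("FA_global_", 1:5))
  img_load <- matrix(0, length(img_vars), 3, dimnames = list(img_vars, NULL))
  img_load[1:6, 1] <- 0.85                      # motor system / neurogenesis
  img_load[7:11, 2] <- 0.8
  img_load[12:16, 3] <- 0.75
  list(
    cytokines = biomarker_spec(cyto_load,
                               responder_effect = c(-responder_sd_shift, 0, 0),
                               timepoints = c(0, 3, 6, 9, 12), seed = 31L),
    hematology = biomarker_spec(hema_load,
                                responder_effect = c(responder_sd_shift, 0, 0),
                                ordinal_vars = c(mobilization_grade = 5L,
                                                 tolerability_grade = 4L),
                                timepoints = c(0, 3, 6, 12), seed = 32L),
    imaging = biomarker_spec(img_load,
                             responder_effect = c(responder_sd_shift, 0, 0),
                             timepoints = 12, seed = 33L)
  )
}
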