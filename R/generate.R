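# Synthetic cohort, trajectory and biomarker generators. These stand in for the
# access-restricted historical-control database and the treated clinical
# cohort; they produce the same table shapes the analysis stages consume.

draw_covariates <- function(spec, cohort, id_prefix) {
  n <- spec$n_patients
  data.frame(
    patient_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    cohort = cohort,
    age = clip(stats::rnorm(n, spec$age_mean, spec$age_sd), 18, 95),
    sex = ifelse(stats::runif(n) < spec$frac_female, "female", "male"),
    onset_site = ifelse(stats::runif(n) < spec$frac_bulbar, "bulbar", "limb"),
    baseline_alsfrs = clip(round(stats::rnorm(n, spec$baseline_alsfrs_mean,
                                              spec$baseline_alsfrs_sd)), 0, 48),
    latency_days = clip(stats::rnorm(n, spec$latency_mean, spec$latency_sd),
                        30, Inf),
    riluzole = as.integer(stats::runif(n) < spec$riluzole_prob),
    stringsAsFactors = FALSE
  )
}

draw_event_times <- function(spec, covars) {
  lp <- rep(0, nrow(covars))
  betas <- spec$log_hazard_betas
  if (length(betas)) {
    x <- cbind(age = covars$age,
               female = as.numeric(covars$sex == "female"),
               bulbar = as.numeric(covars$onset_site == "bulbar"),
               baseline_alsfrs = covars$baseline_alsfrs,
               latency_days = covars$latency_days,
               riluzole = covars$riluzole)
    lp <- drop(x[, names(betas), drop = FALSE] %*% betas)
  }
  rate <- spec$baseline_hazard * exp(lp)
  if (spec$weibull_shape == 1) {
    stats::rexp(nrow(covars), rate)
  } else {
    # Weibull extension, S(t) = exp(-(rate * t)^k): shape 1 is the exponential
    # default; covariates accelerate time through the rate.
    (-log(stats::runif(nrow(covars))))^(1 / spec$weibull_shape) / rate
  }
}

apply_censoring <- function(df, t_event, window) {
  df$survival_days <- pmin(t_event, window)
  df$event <- t_event <= window
  df
}

#' Generate a synthetic historical-control cohort
#'
#' Draws covariates and exponential survival times with administrative
#' censoring, reproducibly for a given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param cohort cohort label stored in the table.
#' @param id_prefix prefix for patient identifiers.
#' @return a data frame with one row per patient: identifiers, covariates,
#'   `survival_days` and logical `event` (FALSE exactly when the censoring
#'   window binds).
#' @examples
#' ctrl <- generate_control_cohort(cohort_spec(n_patients = 100, seed = 7))
#' @export
generate_control_cohort <- function(spec, cohort = "control", id_prefix = "C") {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  with_seed(spec$seed, {
    covars <- draw_covariates(spec, cohort, id_prefix)
    t_event <- draw_event_times(spec, covars)
    apply_censoring(covars, t_event, spec$censor_window)
  })
}

#' Generate a synthetic treated cohort with latent responder structure
#'
#' As [generate_control_cohort()], but each patient carries a latent responder
#' flag (probability depending on `responder_fraction` and the age
#' interaction); responder event times are multiplied by `responder_etr`
#' before censoring. The latent flags are returned separately from the patient
#' table: analysis stages must never join them; only test code and explicit
#' recovery checks may.
#'
#' @param spec a [treated_spec()].
#' @return a list of class `treated_cohort` with elements `patients` (table as
#'   in [generate_control_cohort()]) and `latent` (data frame `patient_id`,
#'   `latent_responder`).
#' @export
generate_treated_cohort <- function(spec) {
  if (!inherits(spec, "treated_spec")) stop("`spec` must be a treated_spec", call. = FALSE)
  base <- spec$base
  with_seed(base$seed, {
    covars <- draw_covariates(base, "treated", "T")
    t_event <- draw_event_times(base, covars)
    p_resp <- stats::plogis(stats::qlogis(spec$responder_fraction) +
                              spec$age_interaction * (covars$age - base$age_mean))
    if (spec$responder_fraction == 0) p_resp <- rep(0, nrow(covars))
    if (spec$responder_fraction == 1) p_resp <- rep(1, nrow(covars))
    flag <- stats::runif(nrow(covars)) < p_resp
    t_event[flag] <- t_event[flag] * spec$responder_etr
    patients <- apply_censoring(covars, t_event, base$censor_window)
    structure(list(patients = patients,
                   latent = data.frame(patient_id = patients$patient_id,
                                       latent_responder = flag,
                                       stringsAsFactors = FALSE)),
              class = "treated_cohort")
  })
}

#' Generate longitudinal ALSFRS-R trajectories
#'
#' Per-patient linear decline with a floor, visit-level noise, and truncation
#' at death/censoring: a visit at month `m` is kept only when `m * 30.44`
#' days is strictly less than the patient's `survival_days`. Responder slopes
#' (if `responder` flags are supplied) are attenuated by
#' `spec$responder_slope_attenuation`.
#'
#' @param patients patient table with `patient_id`, `baseline_alsfrs`,
#'   `survival_days`.
#' @param spec a [trajectory_spec()].
#' @param responder optional logical vector (or data frame `patient_id`,
#'   `latent_responder`) marking responders.
#' @param seed integer RNG seed.
#' @return visit table: `patient_id`, `month`, `alsfrs`.
#' @export
generate_trajectories <- function(patients, spec, responder = NULL, seed = 11L) {
  if (!inherits(spec, "trajectory_spec")) stop("`spec` must be a trajectory_spec", call. = FALSE)
  if (is.null(patients$baseline_alsfrs) || anyNA(patients$baseline_alsfrs)) {
    stop("every patient needs a baseline ALSFRS-R value", call. = FALSE)
  }
  if (is.data.frame(responder)) {
    responder <- responder$latent_responder[match(patients$patient_id, responder$patient_id)]
  }
  if (is.null(responder)) responder <- rep(FALSE, nrow(patients))
  with_seed(seed, {
    n <- nrow(patients)
    slope <- stats::rnorm(n, spec$slope_mean, spec$slope_sd)
    slope[responder] <- slope[responder] * spec$responder_slope_attenuation
    vm <- spec$visit_months
    # visits strictly before death/censoring
    n_vis <- findInterval(patients$survival_days, months_to_days(vm),
                          left.open = TRUE)
    idx <- rep.int(seq_len(n), n_vis)
    month <- unlist(lapply(n_vis, function(k) vm[seq_len(k)]), use.names = FALSE)
    score <- patients$baseline_alsfrs[idx] + slope[idx] * month +
      stats::rnorm(length(idx), 0, spec$noise_sd)
    data.frame(patient_id = patients$patient_id[idx], month = month,
               alsfrs = clip(score, spec$floor, 48),
               stringsAsFactors = FALSE)
  })
}

#' Generate multimodal biomarker panels
#'
#' Linear factor model per timepoint with patient-level persistence: the
#' factor score of patient i at timepoint t is
#' `rho * u_i + sqrt(1 - rho^2) * e_it + responder_effect * flag_i`, values
#' are `loadings %*% scores + noise`. Ordinal variables are discretised into
#' their stated number of quantile bins; entries are then deleted completely
#' at random at `missing_rate`.
#'
#' @param patients patient table (only `patient_id` is used).
#' @param spec a [biomarker_spec()].
#' @param responder logical vector or data frame as in
#'   [generate_trajectories()].
#' @return named list (one element per timepoint, names `"t<months>"`) of data
#'   frames `patient_id` + one column per variable.
#' @export
generate_biomarkers <- function(patients, spec, responder = NULL) {
  if (!inherits(spec, "biomarker_spec")) stop("`spec` must be a biomarker_spec", call. = FALSE)
  if (is.data.frame(responder)) {
    responder <- responder$latent_responder[match(patients$patient_id, responder$patient_id)]
  }
  if (is.null(responder)) responder <- rep(FALSE, nrow(patients))
  L <- spec$loading_matrix
  n <- nrow(patients); p <- nrow(L); k <- ncol(L)
  rho <- spec$within_patient_cor
  with_seed(spec$seed, {
    u <- matrix(stats::rnorm(n * k), n, k)  # patient-level factor anchors
    panels <- list()
    for (tp in spec$timepoints) {
      e <- matrix(stats::rnorm(n * k), n, k)
      f <- rho * u + sqrt(1 - rho^2) * e
      # response-linked shifts are treatment effects: they appear only after
      # baseline (timepoint 0 stays exchangeable between the groups)
      if (tp > 0) f <- f + outer(as.numeric(responder), spec$responder_effect)
      x <- f %*% t(L) + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
      colnames(x) <- rownames(L)
      for (v in names(spec$ordinal_vars)) {
        b <- spec$ordinal_vars[[v]]
        br <- unique(stats::quantile(x[, v], probs = seq(0, 1, length.out = b + 1)))
        x[, v] <- as.integer(cut(x[, v], breaks = br, include.lowest = TRUE))
      }
      if (spec$missing_rate > 0) {
        x[matrix(stats::runif(n * p) < spec$missing_rate, n, p)] <- NA
      }
      panels[[paste0("t", tp)]] <- data.frame(patient_id = patients$patient_id,
                                              x, stringsAsFactors = FALSE,
                                              check.names = FALSE)
    }
    panels
  })
}
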