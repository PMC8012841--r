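# Shared fixtures and small independent oracles used across test files.

tucker_congruence <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}

# a plain 36-patient treated spec mirroring the default study conditions but
# with an explicit seed per test
treated_spec_36 <- function(seed, responder_fraction = 15 / 36,
                            responder_etr = 2.5, age_interaction = -0.06,
                            censor_window = 2400, n = 36L) {
  treated_spec(base = cohort_spec(n_patients = n, age_mean = 51.9,
                                  age_sd = 10.5, frac_female = 0.306,
                                  frac_bulbar = 8 / 36,
                                  baseline_alsfrs_mean = 37.6,
                                  baseline_alsfrs_sd = 5.7,
                                  latency_mean = 595, latency_sd = 350,
                                  censor_window = censor_window, seed = seed),
               responder_fraction = responder_fraction,
               responder_etr = responder_etr,
               age_interaction = age_interaction)
}

# two-arm exponential sample with a hazard ratio on the second arm
two_arm_exp <- function(n_per_arm, hr = 1, rate0 = 1 / 300, censor = Inf,
                        seed = NULL) {
  draw <- function() {
    t0 <- stats::rexp(n_per_arm, rate0)
    t1 <- stats::rexp(n_per_arm, rate0 * hr)
    tt <- c(t0, t1)
    data.frame(time = pmin(tt, censor), event = tt <= censor,
               group = factor(rep(c("control", "treated"), each = n_per_arm),
                              levels = c("control", "treated")))
  }
  if (is.null(seed)) draw() else alsresponder:::with_seed(seed, draw())
}

# independently coded exponential log-likelihood for the reciprocal-link GLM
expsurv_loglik_oracle <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  if (any(eta <= 0)) return(-Inf)
  sum(log(eta)) - sum(y * eta)
}
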