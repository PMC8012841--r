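# The reciprocal-link exponential survival model and residual-based
# responder classification.

test_that("intercept-only fit equals the closed-form exponential MLE", {
  set.seed(71)
  d <- data.frame(t = rexp(200, 1 / 350))
  fit <- expsurv(t ~ 1, d)
  expect_equal(1 / unname(coef(fit)[["(Intercept)"]]), mean(d$t))
  expect_true(all(predict(fit) == predict(fit)[1]))
})

test_that("coefficients match a direct numerical maximization on a 50-patient toy set", {
  set.seed(72)
  n <- 50
  x <- runif(n)
  eta <- 0.002 + 0.003 * x
  d <- data.frame(t = rexp(n, eta), x = x)
  fit <- expsurv(t ~ x, d)
  X <- cbind(1, x)
  ora <- optim(c(1 / mean(d$t), 0),
               function(b) -expsurv_loglik_oracle(b, X, d$t),
               method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000,
                              parscale = c(1e-3, 1e-3)))
  expect_equal(unname(coef(fit)), ora$par, tolerance = 1e-3)
  expect_equal(fit$logLik, -ora$value, tolerance = 1e-8)
})

test_that("the fit agrees with the Gamma-family GLM oracle", {
  set.seed(73)
  n <- 1000
  x1 <- runif(n); x2 <- rnorm(n)
  eta <- 0.003 + 0.002 * x1 - 0.0005 * x2
  d <- data.frame(t = rexp(n, eta), x1 = x1, x2 = x2)
  fit <- expsurv(t ~ x1 + x2, d)
  ora <- glm(t ~ x1 + x2, family = Gamma(link = "inverse"), data = d)
  expect_equal(unname(coef(fit)), unname(coef(ora)), tolerance = 1e-6)
  # dispersion of the exponential is 1: standard errors match that oracle
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(ora, dispersion = 1)))), tolerance = 1e-4)
})

test_that("true coefficients are recovered within two standard errors", {
  set.seed(74)
  n <- 2000
  beta <- c(0.002, 0.0015, -0.0008)
  x1 <- runif(n); x2 <- runif(n)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  d <- data.frame(t = rexp(n, eta), x1 = x1, x2 = x2)
  fit <- expsurv(t ~ x1 + x2, d)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - beta) <= 2 * se))
})

test_that("prediction is a pure function, calibrated, and flags the unpredictable", {
  set.seed(75)
  n <- 3000
  x <- runif(n)
  eta <- 0.002 + 0.002 * x
  d <- data.frame(t = rexp(n, eta), x = x)
  fit <- expsurv(t ~ x, d[1:1500, ])
  held <- d[1501:3000, ]
  mu <- predict(fit, held)
  expect_lt(abs(mean(held$t - mu)) / mean(held$t), 0.1)  # near-zero mean residual
  expect_identical(predict(fit, held[7, ]), predict(fit, held[7, ]))
  # missing covariate: per-patient NA, not a failure
  held$x[1] <- NA
  mu2 <- predict(fit, held)
  expect_true(is.na(mu2[1]))
  expect_equal(attr(mu2, "n_unpredictable"), 1L)
  # a wildly out-of-range covariate drives the predictor nonpositive
  crazy <- data.frame(x = -100)
  expect_true(is.na(predict(fit, crazy)[1]))
})

test_that("training wrapper enforces deceased-only slopes and the 10x rule", {
  set.seed(76)
  ctrl <- generate_control_cohort(cohort_spec(n_patients = 300, seed = 77))
  visits <- generate_trajectories(ctrl, trajectory_spec(), seed = 78)
  sl <- slope_table(visits, max_month = 3)
  fit <- fit_survival_glm(ctrl, sl)
  expect_s3_class(fit, "expsurv")
  small <- ctrl[1:20, ]
  expect_error(fit_survival_glm(small, sl), "training set too small")
})

test_that("classification rules cover the residual/censoring cases", {
  lab <- classify_response(observed = c(500, 900, 300, 430, 420),
                           censored = c(FALSE, TRUE, FALSE, TRUE, FALSE),
                           predicted = c(500, 450, 450, 450, 450),
                           threshold = 60,
                           patient_id = paste0("P", 1:5))
  expect_equal(as.character(lab$label),
               c("non-assignable",   # residual 0
                 "responder",        # censored but already 2x predicted
                 "non-responder",    # died far short
                 "non-assignable",   # censored, shortfall unprovable
                 "non-assignable"))  # within the band
  expect_false(anyNA(lab$label))     # labels partition the patients
  expect_error(classify_response(1, FALSE, 1, threshold = -5), "threshold")
})

test_that("classification is monotone in observed survival", {
  set.seed(79)
  for (i in 1:50) {
    pred <- runif(1, 200, 800)
    obs <- sort(runif(2, 50, 1500))
    cens <- sample(c(TRUE, FALSE), 1)
    l1 <- classify_response(obs[1], cens, pred)$label
    l2 <- classify_response(obs[2], cens, pred)$label
    rank_of <- c("non-responder" = 1, "non-assignable" = 2, "responder" = 3)
    expect_gte(rank_of[[as.character(l2)]], rank_of[[as.character(l1)]])
  }
})

test_that("waterfall orders residuals with stable tie handling", {
  lab <- classify_response(observed = c(400, 250, 300, 300),
                           censored = FALSE,
                           predicted = c(300, 300, 300, 300),
                           threshold = 60,
                           patient_id = c("d", "c", "b", "a"))
  w <- waterfall(lab)
  expect_equal(w$residual, c(100, 0, 0, -50))
  expect_equal(w$patient_id, c("d", "a", "b", "c"))  # ties by id
  expect_setequal(w$patient_id, lab$patient_id)      # content preserving
  expect_error(waterfall(lab[0, ]), "at least one")
})

test_that("self-training residuals are near zero on average", {
  set.seed(80)
  ctrl <- generate_control_cohort(cohort_spec(n_patients = 2000, seed = 81,
                                              censor_window = Inf))
  visits <- generate_trajectories(ctrl, trajectory_spec(), seed = 82)
  fit <- fit_survival_glm(ctrl, slope_table(visits, max_month = 3))
  expect_lt(abs(mean(residuals(fit))) / mean(fit$y), 0.05)
})

test_that("classifying with the generator's own means matches the closed-form oracle", {
  # Use the true per-patient mean: label probabilities follow the exponential
  # closed form, so the empirical accuracy among assignable patients must
  # match the analytically computed expectation.
  set.seed(83)
  n <- 4000; etr <- 2.5; thr <- 60
  mu <- runif(n, 300, 800)
  resp <- runif(n) < 0.5
  obs <- rexp(n, 1 / mu) * ifelse(resp, etr, 1)
  lab <- classify_response(obs, censored = FALSE, predicted = mu, threshold = thr)
  keep <- lab$label != "non-assignable"
  acc <- mean((lab$label[keep] == "responder") == resp[keep])
  # oracle: P(correct)/P(assignable) integrated over patients
  p_resp_correct <- exp(-(mu + thr) / (etr * mu))
  p_resp_wrong <- 1 - exp(-pmax(mu - thr, 0) / (etr * mu))
  p_non_correct <- 1 - exp(-pmax(mu - thr, 0) / mu)
  p_non_wrong <- exp(-(mu + thr) / mu)
  acc_oracle <- (0.5 * mean(p_resp_correct) + 0.5 * mean(p_non_correct)) /
    (0.5 * mean(p_resp_correct + p_resp_wrong) +
       0.5 * mean(p_non_correct + p_non_wrong))
  expect_equal(acc, acc_oracle, tolerance = 0.03)
})

test_that("simulate() draws reproduce the fitted means", {
  set.seed(84)
  d <- data.frame(t = rexp(500, 1 / 400))
  fit <- expsurv(t ~ 1, d)
  sims <- simulate(fit, nsim = 20, seed = 85)
  expect_equal(mean(as.matrix(sims)), mean(d$t), tolerance = 0.05)
})

test_that("survival contrast separates synthetic responders and handles degeneracy", {
  set.seed(86)
  n <- 120
  resp <- rep(c(TRUE, FALSE), each = n / 2)
  mu <- 450
  obs <- rexp(n, 1 / mu) * ifelse(resp, 2.5, 1)
  lab <- classify_response(obs, censored = FALSE, predicted = rep(mu, n),
                           threshold = 60)
  ctr <- response_survival_contrast(lab)
  expect_gt(ctr$medians[["responder"]], ctr$medians[["non-responder"]])
  expect_true(ctr$p_defined)
  expect_lt(ctr$p_value, 0.05)
  # single patient per group: p undefined, not an error
  tiny <- classify_response(c(1000, 100), c(FALSE, FALSE), c(500, 500), 60)
  ctr2 <- response_survival_contrast(tiny)
  expect_false(ctr2$p_defined)
  expect_true(is.na(ctr2$p_value))
})
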