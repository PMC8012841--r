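# Kaplan-Meier, weighted log-rank, Cox, parametric and AFT fits.

test_that("product-limit steps and median match the hand calculation", {
  km <- km_estimate(c(100, 200, 300), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 200)
  expect_true(km$median_defined)
})

test_that("a fully censored sample has S = 1 and an undefined median", {
  km <- km_estimate(c(50, 80, 120), c(FALSE, FALSE, FALSE))
  expect_true(all(km$surv == 1))
  expect_false(km$median_defined)
  expect_true(is.na(km$median))
})

test_that("KM estimation rejects empty or nonpositive input", {
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(TRUE, TRUE)), "positive")
})

test_that("the KM curve is invariant to sample order and equivariant to time scaling", {
  set.seed(31)
  tt <- rexp(200, 1 / 300); ev <- tt < 500; tt <- pmin(tt, 500)
  km1 <- km_estimate(tt, ev)
  ord <- sample(200)
  km2 <- km_estimate(tt[ord], ev[ord])
  expect_equal(km1$surv, km2$surv)
  expect_equal(km1$median, km2$median)
  km3 <- km_estimate(3 * tt, ev)
  expect_equal(km3$median, 3 * km1$median)
  expect_true(all(diff(km1$surv) <= 0))
  expect_true(all(km1$lower <= km1$surv + 1e-12 & km1$surv <= km1$upper + 1e-12,
                  na.rm = TRUE))
})

test_that("log-rank statistic matches the hand-computed observed-minus-expected form", {
  # arm A events at 1, 2; arm B events at 3, 4 - computed by hand:
  # event times 1,2,3,4 with n = 4,3,2,1 at risk; nA = 2,1,0,0
  # O_A = 2, E_A = 2/4 + 1/3 = 5/6, V_A = sum d(n-d)/(n-1) * pA(1-pA)
  tt <- c(1, 2, 3, 4); ev <- rep(TRUE, 4); g <- c("A", "A", "B", "B")
  ea <- 2 / 4 + 1 / 3
  va <- (2 / 4) * (1 - 2 / 4) + (1 / 3) * (1 - 1 / 3)
  lr <- logrank_test(tt, ev, g)
  expect_equal(lr$statistic, (2 - ea)^2 / va)
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(unname(lr$expected["A"]), ea)
})

test_that("log-rank agrees with the survdiff oracle; Gehan weights with a direct sum", {
  set.seed(32)
  d <- two_arm_exp(60, hr = 1.6, censor = 500)
  lr <- logrank_test(d$time, d$event, d$group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  # independent Gehan computation: weight = n at risk at each event time
  wx <- logrank_test(d$time, d$event, d$group, variant = "wilcoxon")
  u <- 0; v <- 0
  for (tj in sort(unique(d$time[d$event]))) {
    at <- d$time >= tj
    nj <- sum(at); n1 <- sum(at & d$group == "control")
    dj <- sum(d$event & d$time == tj)
    d1 <- sum(d$event & d$time == tj & d$group == "control")
    u <- u + nj * (d1 - dj * n1 / nj)
    if (nj > 1) v <- v + nj^2 * dj * (nj - dj) / (nj - 1) * (n1 / nj) * (1 - n1 / nj)
  }
  expect_equal(wx$statistic, u^2 / v, tolerance = 1e-10)
})

test_that("identical duplicated groups give statistic 0 and a single group errors", {
  tt <- c(100, 200, 300); ev <- c(TRUE, TRUE, FALSE)
  lr <- logrank_test(c(tt, tt), c(ev, ev), rep(c("A", "B"), each = 3))
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(tt, ev, rep("A", 3)), "two groups")
})

test_that("Cox coefficient is zero for mirrored groups and errors on a constant covariate", {
  d <- data.frame(time = rep(c(100, 200, 300, 400), 2),
                  event = TRUE,
                  group = rep(c("A", "B"), each = 4))
  fit <- cox_fit(survival::Surv(time, event) ~ group, d)
  expect_lt(abs(fit$coefficients[["groupB"]]), 1e-8)
  d$flat <- 1
  expect_error(cox_fit(survival::Surv(time, event) ~ group + flat, d), "flat")
})

test_that("Cox matches a grid search of the partial likelihood on a toy set", {
  # 8 subjects, distinct times (no ties), one binary covariate
  d <- data.frame(time = c(30, 60, 90, 150, 210, 300, 420, 600),
                  event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
                  x = c(1, 1, 0, 1, 0, 0, 1, 0))
  fit <- cox_fit(survival::Surv(time, event) ~ x, d)
  # independent partial likelihood and grid maximization
  plik <- function(b) {
    ll <- 0
    for (i in which(d$event)) {
      rs <- d$time >= d$time[i]
      ll <- ll + b * d$x[i] - log(sum(exp(b * d$x[rs])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, plik, numeric(1)))]
  expect_equal(unname(fit$coefficients[["x"]]), b_grid, tolerance = 1e-3)
})

test_that("Cox recovers a true hazard ratio of 2 and is shift invariant", {
  d <- two_arm_exp(1000, hr = 2, censor = 900, seed = 33)
  fit <- cox_fit(survival::Surv(time, event) ~ group, d)
  expect_gt(fit$hazard_ratios[["grouptreated"]], 1.8)
  expect_lt(fit$hazard_ratios[["grouptreated"]], 2.2)
  expect_equal(fit$hazard_ratios[["grouptreated"]],
               exp(fit$coefficients[["grouptreated"]]))
  # additive covariate shifts leave the coefficient unchanged
  d$z <- as.numeric(d$group == "treated")
  f1 <- cox_fit(survival::Surv(time, event) ~ z, d)
  d$z <- d$z + 100
  f2 <- cox_fit(survival::Surv(time, event) ~ z, d)
  expect_equal(f1$coefficients[["z"]], f2$coefficients[["z"]], tolerance = 1e-6)
})

test_that("null parametric fit is the closed-form exponential rate MLE", {
  set.seed(34)
  tt <- rexp(400, 1 / 250); ev <- tt < 600; tt <- pmin(tt, 600)
  d <- data.frame(time = tt, event = ev)
  fit <- parametric_fit(survival::Surv(time, event) ~ 1, d)
  expect_equal(exp(fit$coefficients[["(Intercept)"]]), sum(ev) / sum(tt),
               tolerance = 1e-6)
  # log-likelihood at the MLE beats perturbed coefficient vectors
  ll <- function(lograte) sum(ev) * lograte - exp(lograte) * sum(tt)
  expect_gte(ll(fit$coefficients[["(Intercept)"]]) + 1e-8,
             max(ll(fit$coefficients[["(Intercept)"]] + c(-0.1, -0.01, 0.01, 0.1))))
})

test_that("parametric fit recovers an interaction and agrees with Cox on exponential data", {
  set.seed(35)
  n <- 2000
  grp <- rep(0:1, each = n / 2)
  age <- rnorm(n, 60, 10)
  b_int <- 0.03
  rate <- (1 / 300) * exp(0.4 * grp + 0.02 * (age - 60) + b_int * grp * (age - 60))
  tt <- rexp(n, rate); ev <- tt < 900; tt <- pmin(tt, 900)
  d <- data.frame(time = tt, event = ev, grp = grp, agec = age - 60)
  fit <- parametric_fit(survival::Surv(time, event) ~ grp * agec, d)
  est <- fit$coefficients[["grp:agec"]]
  se <- fit$se[["grp:agec"]]
  expect_lt(abs(est - b_int), 2 * se)
  # model-agreement property on plain exponential PH data
  d5 <- two_arm_exp(2500, hr = 2, censor = 1200, seed = 36)
  cx <- cox_fit(survival::Surv(time, event) ~ group, d5)
  pm <- parametric_fit(survival::Surv(time, event) ~ group, d5)
  expect_lt(abs(cx$coefficients[["grouptreated"]] -
                  pm$coefficients[["grouptreated"]]), 0.05)
})

test_that("AFT fit reports event-time ratios that invert the acceleration", {
  # null effect
  d0 <- two_arm_exp(800, hr = 1, censor = 1200, seed = 37)
  f0 <- aft_fit(survival::Surv(time, event) ~ group, d0)
  expect_equal(unname(f0$event_time_ratio[["grouptreated"]]), 1, tolerance = 0.12)
  # true time-acceleration factor 0.5 on the treated arm
  d1 <- two_arm_exp(1000, hr = 2, censor = Inf, seed = 38)  # exponential: ETR = 1/HR
  f1 <- aft_fit(survival::Surv(time, event) ~ group, d1)
  expect_gt(f1$event_time_ratio[["grouptreated"]], 0.45)
  expect_lt(f1$event_time_ratio[["grouptreated"]], 0.55)
})

test_that("log-rank type-I error is nominal under the null", {
  set.seed(39)
  p <- replicate(500, {
    d <- two_arm_exp(50, hr = 1, censor = 600)
    logrank_test(d$time, d$event, d$group)$p_value
  })
  expect_gt(mean(p < 0.05), 0.025)
  expect_lt(mean(p < 0.05), 0.075)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})
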