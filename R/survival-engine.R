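# Survival engine: Kaplan-Meier estimation, weighted log-rank tests, Cox
# proportional hazards, fully parametric exponential fits and AFT fits with
# event-time ratios. Model fitting delegates to the survival package; the
# weighted log-rank statistic is computed directly (the Wilcoxon variant uses
# Gehan at-risk-count weights, which survdiff does not expose).

check_surv_input <- function(time, event) {
  if (length(time) < 1L) stop("empty survival input", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  if (length(event) != length(time)) stop("`time` and `event` lengths differ", call. = FALSE)
  invisible(NULL)
}

#' Kaplan-Meier estimate with pointwise confidence intervals
#'
#' Product-limit estimate with Greenwood-based pointwise 95% intervals on the
#' log-log scale. The median is the earliest time at which the survival curve
#' drops to 0.5 or below; when the curve never reaches 0.5 the median is `NA`
#' and `median_defined` is `FALSE`.
#'
#' @param time positive follow-up times (days).
#' @param event logical/0-1 event indicator (`FALSE` = censored).
#' @param conf_level confidence level for the pointwise intervals.
#' @return object of class `km_curve`: step `time`s, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper`, `median`, `median_ci`, `median_defined`, `n`.
#' @examples
#' km <- km_estimate(c(100, 200, 300), c(TRUE, TRUE, TRUE))
#' km$median  # 200
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv, lower = fit$lower, upper = fit$upper,
                 median = med,
                 median_ci = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
                 median_defined = !is.na(med),
                 n = length(time), events = sum(as.integer(event))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$events))
  if (x$median_defined) {
    cat(sprintf("  median survival %.1f days (95%% CI %.1f-%.1f)\n",
                x$median, x$median_ci[1], x$median_ci[2]))
  } else {
    cat("  median survival not reached\n")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, conf = TRUE, xlab = "Days", ylab = "Survival", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  if (conf) {
    graphics::lines(stats::stepfun(x$time, c(1, x$lower)), do.points = FALSE, lty = 3)
    graphics::lines(stats::stepfun(x$time, c(1, x$upper)), do.points = FALSE, lty = 3)
  }
  invisible(x)
}

#' Weighted log-rank test across two or more groups
#'
#' Chi-square test on g-1 degrees of freedom of the weighted
#' observed-minus-expected event counts, with hypergeometric covariance.
#' `variant = "logrank"` uses unit weights; `variant = "wilcoxon"` uses the
#' generalized Wilcoxon (Gehan) weights, i.e. the total number at risk at
#' each event time.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 distinct values).
#' @param variant `"logrank"` or `"wilcoxon"`.
#' @return list: `statistic`, `df`, `p_value`, `observed`, `expected`,
#'   `variant`.
#' @export
logrank_test <- function(time, event, group, variant = c("logrank", "wilcoxon")) {
  variant <- match.arg(variant)
  check_surv_input(time, event)
  group <- factor(group)
  g <- nlevels(group)
  if (g < 2L) stop("at least two groups are required", call. = FALSE)
  event <- as.integer(event)
  if (sum(event) < 1L) stop("at least one event is required", call. = FALSE)

  dtimes <- sort(unique(time[event == 1L]))
  O <- E <- numeric(g)
  V <- matrix(0, g, g)
  for (tj in dtimes) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    nij <- tabulate(group[at_risk], nbins = g)
    died <- event == 1L & time == tj
    dj <- sum(died)
    dij <- tabulate(group[died], nbins = g)
    w <- if (variant == "wilcoxon") nj else 1
    O <- O + w * dij
    E <- E + w * dj * nij / nj
    if (nj > 1) {
      hyp <- dj * (nj - dj) / (nj - 1) *
        (diag(nij / nj, g) - tcrossprod(nij / nj))
      V <- V + w^2 * hyp
    }
  }
  idx <- seq_len(g - 1L)
  u <- (O - E)[idx]
  vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(vi, u)), error = function(e) 0)
  structure(list(statistic = stat, df = g - 1L,
                 p_value = stats::pchisq(stat, g - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group)),
                 variant = variant),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("%s test: chisq = %.3f on %d df, p = %.4g\n",
              if (x$variant == "wilcoxon") "Gehan-Wilcoxon" else "Log-rank",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

new_surv_fit <- function(model, coefficients, se, hazard_ratios, etr, loglik,
                         fit, extra = list()) {
  wald <- (coefficients / se)^2
  structure(c(list(model = model, coefficients = coefficients, se = se,
                   hazard_ratios = hazard_ratios, event_time_ratio = etr,
                   wald_chisq = wald,
                   p = stats::pchisq(wald, 1, lower.tail = FALSE),
                   log_likelihood = loglik, fit = fit), extra),
            class = "surv_fit")
}

#' @export
print.surv_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s survival fit (log-likelihood %.2f)\n", x$model, x$log_likelihood))
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    `Wald chisq` = x$wald_chisq, p = x$p, check.names = FALSE)
  if (!is.null(x$hazard_ratios)) tab$HR <- x$hazard_ratios[names(x$coefficients)]
  if (!is.null(x$event_time_ratio)) tab$ETR <- x$event_time_ratio[names(x$coefficients)]
  print(round(tab, digits))
  invisible(x)
}

check_nonconstant_covariates <- function(mm) {
  keep <- colnames(mm)[colnames(mm) != "(Intercept)"]
  for (cn in keep) {
    if (stats::var(mm[, cn]) == 0) {
      stop(sprintf("constant covariate '%s'", cn), call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Cox proportional-hazards fit with Wald tests
#'
#' Partial-likelihood fit (Efron tie handling) with per-covariate Wald
#' chi-square statistics and p-values.
#'
#' @param formula a formula `Surv(time, event) ~ covariates`.
#' @param data data frame holding the variables.
#' @return a `surv_fit` object with log-hazard `coefficients` and
#'   `hazard_ratios = exp(coefficients)`.
#' @export
cox_fit <- function(formula, data) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(formula, data = data)), data)
  check_nonconstant_covariates(mm)
  fit <- survival::coxph(formula, data = data, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    stop("Cox fit failed to converge: ", paste(fit$iter, collapse = " "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  new_surv_fit("Cox proportional hazards", cf, se, exp(cf), NULL,
               fit$loglik[2], fit)
}

#' Parametric exponential survival fit
#'
#' Full maximum-likelihood fit under the exponential law, reported on the
#' log-hazard scale so coefficient signs agree with [cox_fit()]. Interaction
#' terms are supported through the formula.
#'
#' @inheritParams cox_fit
#' @return a `surv_fit` object; `coefficients` includes the intercept
#'   (log baseline hazard).
#' @export
parametric_fit <- function(formula, data) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(formula, data = data)), data)
  check_nonconstant_covariates(mm)
  fit <- survival::survreg(formula, data = data, dist = "exponential")
  cf <- -stats::coef(fit)              # survreg works on the log-time scale
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(cf)]
  names(cf)[1] <- "(Intercept)"
  hr <- exp(cf); hr["(Intercept)"] <- NA
  new_surv_fit("Parametric exponential", cf, se, hr, NULL,
               fit$loglik[2], fit)
}

#' Accelerated failure time fit with event-time ratios
#'
#' Weibull AFT model by default (`dist = "exponential"` available). The
#' event-time ratio of a covariate is `exp(coefficient)` on the log-time
#' scale: values below 1 accelerate the event. Hazard ratios are derived as
#' `exp(-coefficient / scale)`.
#'
#' @inheritParams cox_fit
#' @param dist `"weibull"` (default) or `"exponential"`.
#' @return a `surv_fit` object with `event_time_ratio` per covariate.
#' @export
aft_fit <- function(formula, data, dist = c("weibull", "exponential")) {
  dist <- match.arg(dist)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(formula, data = data)), data)
  check_nonconstant_covariates(mm)
  fit <- survival::survreg(formula, data = data, dist = dist)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(cf)]
  etr <- exp(cf); etr["(Intercept)"] <- NA
  hr <- exp(-cf / fit$scale); hr["(Intercept)"] <- NA
  new_surv_fit(sprintf("AFT (%s)", dist), cf, se, hr, etr,
               fit$loglik[2], fit, extra = list(scale = fit$scale))
}
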