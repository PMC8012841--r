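# The central model: exponential survival regression with a reciprocal link.
# Survival time T_i ~ Exponential(mean mu_i) with mu_i = 1 / (x_i' beta), fit
# by Newton-Raphson on the exact log-likelihood
#   l(beta) = sum_i [ log(x_i' beta) - t_i * (x_i' beta) ],
# which is strictly concave wherever every linear predictor is positive.
# Covariates are standardized internally for the optimizer; reported
# coefficients are on the original scale (units: day^-1 per covariate unit).

#' Exponential survival regression with reciprocal link
#'
#' Fits `time ~ covariates` under an exponential distribution whose mean is
#' the reciprocal of the linear predictor. Intended to be trained on deceased
#' patients of a historical-control cohort and then applied, through
#' [predict.expsurv()], to new patients (including censored ones) to obtain
#' individual expected survival.
#'
#' Starting values come from an ordinary least-squares regression of `1/time`
#' on the covariates (shrunk towards the intercept-only solution until the
#' linear predictor is positive everywhere); Newton steps are halved whenever
#' they would leave the feasible region. Convergence is declared when the
#' relative change in log-likelihood falls below `tol`.
#'
#' @param formula model formula; the response is the survival time in days.
#' @param data data frame with the response and covariates.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `expsurv` with components `coefficients`
#'   (day^-1 scale), `vcov`, `logLik`, `fitted` (expected survival, days),
#'   `converged`, `iterations`, `n`, plus bookkeeping (`call`, `terms`,
#'   `xlevels`).
#' @seealso [fit_survival_glm()] for the deceased-only training wrapper,
#'   [classify_response()] for residual-based responder labels.
#' @examples
#' d <- data.frame(t = rexp(50, 1 / 300))
#' fit <- expsurv(t ~ 1, d)
#' 1 / coef(fit)  # the sample mean: closed-form exponential MLE
#' @export
expsurv <- function(formula, data, tol = 1e-8, max_iter = 100L) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("more coefficients than observations", call. = FALSE)

  # standardize non-intercept columns for the optimizer
  ctr <- rep(0, p); scl <- rep(1, p)
  has_int <- "(Intercept)" %in% colnames(X)
  for (j in seq_len(p)) {
    if (colnames(X)[j] != "(Intercept)") {
      s <- stats::sd(X[, j])
      if (s > 0 && has_int) { ctr[j] <- mean(X[, j]); scl[j] <- s }
    }
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  loglik <- function(b) { eta <- drop(Z %*% b); if (any(eta <= 0)) return(-Inf)
    sum(log(eta)) - sum(y * eta) }

  # feasible start: OLS on 1/y, shrunk to the intercept-only MLE if needed
  b0 <- rep(0, p)
  if (has_int) b0[which(colnames(X) == "(Intercept)")] <- 1 / mean(y)
  bs <- tryCatch(stats::coef(stats::lm.fit(Z, 1 / y)), error = function(e) b0)
  bs[is.na(bs)] <- 0
  b <- bs
  for (s in 0:30) {
    b <- bs * (0.5^s) + b0 * (1 - 0.5^s)
    if (is.finite(loglik(b))) break
  }
  if (!is.finite(loglik(b))) {
    stop("could not find a feasible starting value; consider rescaling covariates",
         call. = FALSE)
  }

  ll <- loglik(b); trace <- numeric(0); converged <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% b)
    grad <- drop(crossprod(Z, 1 / eta - y))
    H <- -crossprod(Z / eta)            # t(Z) %*% diag(-1/eta^2) %*% Z
    step <- tryCatch(solve(H, -grad), error = function(e) NULL)
    if (is.null(step)) stop("singular Hessian in exponential GLM fit", call. = FALSE)
    lam <- 1; ll_new <- -Inf
    for (h in 0:40) {
      bn <- b + lam * step
      ll_new <- loglik(bn)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
    }
    if (!is.finite(ll_new)) {
      stop("linear predictor left the positive region; consider rescaling covariates",
           call. = FALSE)
    }
    b <- bn
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    trace <- c(trace, ll_new)
    ll <- ll_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("exponential GLM did not converge in %d iterations (log-likelihood trace: %s)",
                 max_iter, paste(format(utils::tail(trace, 5), digits = 10), collapse = ", ")),
         call. = FALSE)
  }
  # one polishing Newton step: quadratic convergence squares the residual
  # error left by the log-likelihood stopping rule
  eta <- drop(Z %*% b)
  grad <- drop(crossprod(Z, 1 / eta - y))
  H <- -crossprod(Z / eta)
  polish <- tryCatch(b + solve(H, -grad), error = function(e) b)
  if (is.finite(loglik(polish)) && loglik(polish) >= ll - 1e-10) {
    b <- polish
    ll <- loglik(b)
    eta <- drop(Z %*% b)
    H <- -crossprod(Z / eta)
  }
  if (any(eta <= 0)) {
    stop("nonpositive linear predictor at the optimum; consider rescaling covariates",
         call. = FALSE)
  }
  # back-transform: eta = Z b = X beta with beta_j = b_j/scl_j,
  # beta_0 = b_0 - sum_j b_j ctr_j / scl_j
  beta <- b / scl
  if (has_int) {
    i0 <- which(colnames(X) == "(Intercept)")
    beta[i0] <- b[i0] - sum((b / scl * ctr)[-i0])
  }
  names(beta) <- colnames(X)
  Vz <- solve(-H)
  # delta method is exact here (linear transform)
  A <- diag(1 / scl, p)
  if (has_int) A[which(colnames(X) == "(Intercept)"), ] <-
    as.numeric(colnames(X) == "(Intercept)") - ctr / scl *
      (colnames(X) != "(Intercept)")
  V <- A %*% Vz %*% t(A)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = V, logLik = ll,
                 fitted = 1 / eta, residuals = y - 1 / eta,
                 y = y, converged = converged, iterations = iter,
                 n = n, call = match.call(),
                 formula = formula, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf)),
            class = "expsurv")
}

#' Train the survival-prediction model on deceased historical controls
#'
#' Merges per-patient robust slopes into the patient table, restricts to
#' deceased patients with a defined slope, checks that the training set is at
#' least ten times larger than the coefficient vector, and fits [expsurv()]
#' on `survival_days ~ slope + age + latency_days`.
#'
#' @param patients patient table (`survival_days`, `event`, `age`,
#'   `latency_days`).
#' @param slopes slope table from [slope_table()].
#' @param formula model formula (default the standard three-covariate model).
#' @return an `expsurv` fit with a `training` attribute describing the set.
#' @export
fit_survival_glm <- function(patients, slopes,
                             formula = survival_days ~ slope + age + latency_days) {
  d <- merge(patients, slopes, by = "patient_id")
  d <- d[as.logical(d$event) & !is.na(d$slope), , drop = FALSE]
  p <- length(attr(stats::terms(formula), "term.labels")) + 1L
  if (nrow(d) < 10L * p) {
    stop(sprintf("training set too small: %d deceased patients with defined slopes, need >= %d",
                 nrow(d), 10L * p), call. = FALSE)
  }
  fit <- expsurv(formula, d)
  attr(fit, "training") <- sprintf("%d deceased patients", nrow(d))
  fit
}

#' @export
print.expsurv <- function(x, ...) {
  cat("Exponential survival regression (reciprocal link)\n")
  cat(sprintf("  n = %d, log-likelihood = %.2f, %d Newton iterations\n",
              x$n, x$logLik, x$iterations))
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.expsurv <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, logLik = object$logLik, n = object$n,
              call = object$call)
  class(out) <- "summary.expsurv"
  out
}

#' @export
print.summary.expsurv <- function(x, ...) {
  cat("Exponential survival regression (reciprocal link)\n")
  cat(sprintf("  n = %d, log-likelihood = %.2f\n\n", x$n, x$logLik))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.expsurv <- function(object, ...) object$coefficients

#' @export
vcov.expsurv <- function(object, ...) object$vcov

#' @export
logLik.expsurv <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients), class = "logLik")
}

#' Predict expected survival for new patients
#'
#' Expected survival is the reciprocal of the linear predictor. Patients whose
#' predictor is nonpositive cannot be predicted by the model; they get `NA`
#' and are counted in the `n_unpredictable` attribute so downstream stages can
#' log and exclude them. Missing covariates likewise yield per-patient `NA`s
#' rather than a global failure.
#'
#' @param object an `expsurv` fit.
#' @param newdata data frame with the model covariates; when omitted the
#'   training fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predicted survival times (days) with attribute
#'   `n_unpredictable`.
#' @export
predict.expsurv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  pred <- rep(NA_real_, nrow(newdata))
  vars <- all.vars(tt)
  complete <- stats::complete.cases(newdata[, vars, drop = FALSE])
  if (any(complete)) {
    mf <- stats::model.frame(tt, newdata[complete, , drop = FALSE],
                             xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
    mu <- ifelse(eta > 0, 1 / eta, NA_real_)
    pred[complete] <- mu
  }
  attr(pred, "n_unpredictable") <- sum(is.na(pred))
  pred
}

#' @export
residuals.expsurv <- function(object, ...) object$residuals

#' Simulate survival times from a fitted reciprocal-link exponential model
#'
#' @param object an `expsurv` fit.
#' @param nsim number of simulated datasets.
#' @param seed optional seed.
#' @param newdata optional covariate table (defaults to training fitted
#'   values).
#' @param ... unused.
#' @return data frame with `nsim` columns of exponential draws at the
#'   per-patient predicted means.
#' @export
simulate.expsurv <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  mu <- if (is.null(newdata)) object$fitted else predict(object, newdata)
  draw <- function() stats::rexp(length(mu), rate = 1 / mu)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Calibration plot of observed against model-predicted survival
#'
#' @param x an `expsurv` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.expsurv <- function(x, ...) {
  graphics::plot(x$fitted, x$y, xlab = "Predicted survival (days)",
                 ylab = "Observed survival (days)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
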