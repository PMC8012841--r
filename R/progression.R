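# Functional-decline modelling: robust per-patient ALSFRS-R slopes,
# restricted-cubic-spline time bases and mixed-effects models of decline with
# group x month (and group x month x latency) interactions.

#' Theil-Sen robust slope of a visit series
#'
#' Median of all pairwise `(score difference) / (month difference)` ratios.
#' With fewer than two distinct visit times the slope is undefined (`NA`), not
#' an error, so the patient can stay in downstream tables.
#'
#' @param month visit times in months.
#' @param score scores at those visits.
#' @return list of class `slope_estimate`: `slope` (points/month),
#'   `n_visits`, `method`.
#' @examples
#' robust_slope(c(0, 6), c(40, 34))$slope  # -1
#' @export
robust_slope <- function(month, score) {
  stopifnot(length(month) == length(score))
  ok <- is.finite(month) & is.finite(score)
  month <- month[ok]; score <- score[ok]
  res <- list(slope = NA_real_, n_visits = length(month), method = "theil-sen")
  if (length(unique(month)) >= 2L) {
    i <- utils::combn(length(month), 2L)
    dm <- month[i[2, ]] - month[i[1, ]]
    keep <- dm != 0
    res$slope <- stats::median((score[i[2, ]] - score[i[1, ]])[keep] / dm[keep])
  }
  class(res) <- "slope_estimate"
  res
}

#' Per-patient slope table
#'
#' Applies [robust_slope()] (or ordinary least squares) per patient to a visit
#' table, optionally restricted to an early window.
#'
#' @param visits visit table (`patient_id`, `month`, `alsfrs`).
#' @param max_month keep visits with `month <= max_month` (`Inf` for all).
#' @param method `"theil-sen"` (default) or `"ols"`.
#' @return data frame `patient_id`, `slope`, `n_visits`.
#' @export
slope_table <- function(visits, max_month = Inf, method = c("theil-sen", "ols")) {
  method <- match.arg(method)
  visits <- visits[visits$month <= max_month, , drop = FALSE]
  ids <- unique(visits$patient_id)
  sl <- vapply(split(visits[, c("month", "alsfrs")], factor(visits$patient_id, levels = ids)),
               function(v) {
                 if (method == "theil-sen") return(robust_slope(v$month, v$alsfrs)$slope)
                 if (length(unique(v$month)) < 2L) return(NA_real_)
                 unname(stats::coef(stats::lm(alsfrs ~ month, data = v))[2])
               }, numeric(1))
  nv <- as.integer(table(factor(visits$patient_id, levels = ids)))
  data.frame(patient_id = ids, slope = unname(sl), n_visits = nv,
             stringsAsFactors = FALSE)
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted (natural) cubic spline: linear tails beyond the
#' boundary knots, `n_knots - 2` nonlinear columns plus the linear term.
#' Knots default to the 10th/50th/90th percentiles of the observed values.
#'
#' @param x numeric vector to expand.
#' @param n_knots number of knots (>= 3).
#' @param knots optional explicit knot locations (overrides `n_knots`).
#' @return matrix with columns `x`, `x'`, ... and a `knots` attribute.
#' @export
spline_basis <- function(x, n_knots = 3L, knots = NULL) {
  if (is.null(knots)) {
    n_knots <- check_count(n_knots, "n_knots", min = 3L)
    probs <- if (n_knots == 3L) c(0.1, 0.5, 0.9) else seq(0.05, 0.95, length.out = n_knots)
    knots <- unname(stats::quantile(x, probs, type = 7))
  }
  knots <- sort(unique(knots))
  if (length(knots) < 3L || length(unique(x)) < length(knots) + 1L) {
    stop("too few distinct values for a restricted cubic spline", call. = FALSE)
  }
  K <- length(knots)
  tk <- knots[K]; tk1 <- knots[K - 1]
  norm2 <- (tk - knots[1])^2
  pp <- function(u) pmax(u, 0)^3
  out <- matrix(x, ncol = 1)
  for (j in seq_len(K - 2)) {
    out <- cbind(out, (pp(x - knots[j]) -
                         pp(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                         pp(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm2)
  }
  colnames(out) <- c("x", paste0("x", seq_len(K - 2), "p"))
  attr(out, "knots") <- knots
  out
}

prepare_decline_frame <- function(visits, patients, group_col, max_month) {
  d <- merge(visits, patients, by = "patient_id")
  d <- d[d$month <= max_month, , drop = FALSE]
  d$group <- factor(d[[group_col]])
  d$group <- stats::relevel(d$group, ref = levels(d$group)[1])
  d$sex <- factor(d$sex)
  d
}

fit_lmm_with_fallback <- function(formula_full, formula_fallback, data) {
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(formula_full, data = data, REML = TRUE)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(formula_fallback, data = data, REML = TRUE)))
  }
  list(fit = fit, singular_fallback = singular)
}

#' Mixed-effects spline model of functional decline
#'
#' Linear mixed model of ALSFRS-R on group, a restricted-cubic-spline basis of
#' month, the group-by-month interaction, and baseline covariates, with a
#' per-patient random intercept and slope (REML). A singular random-effects
#' fit triggers an automatic refit with a random intercept only, flagged in
#' the result. The interaction p-value uses Satterthwaite degrees of freedom.
#'
#' @param visits visit table (`patient_id`, `month`, `alsfrs`).
#' @param patients patient table carrying the grouping column and covariates
#'   `baseline_alsfrs`, `age`, `latency_days`, `sex`.
#' @param group_col column of `patients` defining the two groups (first
#'   factor level = reference).
#' @param max_month restrict to visits up to this month (default 6, the
#'   primary early-treatment window).
#' @param eval_month month at which the adjusted group difference is reported.
#' @param n_knots knots for the spline basis of month.
#' @return object of class `decline_fit`: `model`, `coefficients` table,
#'   `interaction_p`, `group_difference` (estimate and SE at `eval_month`),
#'   `prediction_grid`, `singular_fallback`, `knots`.
#' @export
fit_decline <- function(visits, patients, group_col = "cohort", max_month = 6,
                        eval_month = 6, n_knots = 3L) {
  d <- prepare_decline_frame(visits, patients, group_col, max_month)
  if (nlevels(d$group) < 2L) stop("need at least two groups", call. = FALSE)
  sb <- spline_basis(d$month, n_knots = n_knots)
  knots <- attr(sb, "knots")
  for (j in seq_len(ncol(sb) - 1L)) d[[paste0("month_nl", j)]] <- sb[, j + 1L]
  nl_terms <- paste0("month_nl", seq_len(ncol(sb) - 1L), collapse = " + ")
  f_full <- stats::as.formula(paste(
    "alsfrs ~ group * month +", nl_terms,
    "+ baseline_alsfrs + age + latency_days + sex + (1 + month | patient_id)"))
  f_fall <- stats::as.formula(paste(
    "alsfrs ~ group * month +", nl_terms,
    "+ baseline_alsfrs + age + latency_days + sex + (1 | patient_id)"))
  fw <- fit_lmm_with_fallback(f_full, f_fall, d)
  fit <- fw$fit
  ct <- as.data.frame(stats::coef(summary(fit)))
  int_rows <- grep("^group.*:month$", rownames(ct))
  interaction_p <- ct[int_rows, "Pr(>|t|)"]
  names(interaction_p) <- rownames(ct)[int_rows]
  # adjusted group difference at eval_month: beta_group + beta_int * month
  fx <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  g_row <- grep("^group", names(fx))[1]
  i_row <- int_rows[1]
  l <- rep(0, length(fx)); l[g_row] <- 1; l[i_row] <- eval_month
  diff_est <- sum(l * fx)
  diff_se <- sqrt(drop(t(l) %*% vc %*% l))
  grid <- make_prediction_grid(fit, d, knots, max_month)
  structure(list(model = fit, coefficients = ct,
                 interaction_p = interaction_p,
                 group_difference = c(estimate = diff_est, se = diff_se,
                                      month = eval_month),
                 prediction_grid = grid,
                 singular_fallback = fw$singular_fallback,
                 knots = knots),
            class = "decline_fit")
}

make_prediction_grid <- function(fit, d, knots, max_month, latency_at = NULL) {
  months <- seq(0, max_month, by = 0.5)
  ref <- data.frame(month = months)
  sb <- spline_basis(ref$month, knots = knots)
  for (j in seq_len(ncol(sb) - 1L)) ref[[paste0("month_nl", j)]] <- sb[, j + 1L]
  ref$baseline_alsfrs <- mean(d$baseline_alsfrs)
  ref$age <- mean(d$age)
  ref$latency_days <- if (is.null(latency_at)) mean(d$latency_days) else latency_at
  ref$sex <- factor(levels(d$sex)[1], levels = levels(d$sex))
  out <- do.call(rbind, lapply(levels(d$group), function(g) {
    ref$group <- factor(g, levels = levels(d$group))
    ref$pred <- stats::predict(fit, newdata = ref, re.form = NA)
    ref[, c("group", "month", "pred")]
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.decline_fit <- function(x, ...) {
  cat("Mixed-effects decline model",
      if (x$singular_fallback) "(random-intercept fallback)" else "", "\n")
  cat(sprintf("  group x month interaction p: %s\n",
              paste(format(x$interaction_p, digits = 3), collapse = ", ")))
  cat(sprintf("  adjusted group difference at month %g: %.2f (SE %.2f) points\n",
              x$group_difference["month"], x$group_difference["estimate"],
              x$group_difference["se"]))
  invisible(x)
}

#' Decline model with a three-way group x month x latency interaction
#'
#' Extends [fit_decline()] with treatment-latency modification of the
#' group-by-month effect. The group difference in score at `eval_month` is
#' reported over a grid of latencies (months, converted internally to days).
#'
#' @inheritParams fit_decline
#' @param latency_grid_months latencies (months since onset) at which the
#'   adjusted group difference is evaluated; the stated example latency is 10
#'   months.
#' @return a `decline_fit` object with an extra `latency_profile` table
#'   (`latency_months`, `estimate`, `se`) and `threeway_p`.
#' @export
fit_decline_threeway <- function(visits, patients, group_col = "cohort",
                                 max_month = 6, eval_month = 6,
                                 latency_grid_months = c(5, 10, 20),
                                 n_knots = 3L) {
  d <- prepare_decline_frame(visits, patients, group_col, max_month)
  if (nlevels(d$group) < 2L) stop("need at least two groups", call. = FALSE)
  sb <- spline_basis(d$month, n_knots = n_knots)
  knots <- attr(sb, "knots")
  for (j in seq_len(ncol(sb) - 1L)) d[[paste0("month_nl", j)]] <- sb[, j + 1L]
  nl_terms <- paste0("month_nl", seq_len(ncol(sb) - 1L), collapse = " + ")
  f_full <- stats::as.formula(paste(
    "alsfrs ~ group * month * latency_days +", nl_terms,
    "+ baseline_alsfrs + age + sex + (1 + month | patient_id)"))
  f_fall <- stats::as.formula(paste(
    "alsfrs ~ group * month * latency_days +", nl_terms,
    "+ baseline_alsfrs + age + sex + (1 | patient_id)"))
  fw <- fit_lmm_with_fallback(f_full, f_fall, d)
  fit <- fw$fit
  ct <- as.data.frame(stats::coef(summary(fit)))
  fx <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  tw_row <- grep("^group.*:month:latency_days$", names(fx))
  g_row <- grep("^group", names(fx))
  g_main <- g_row[!grepl(":", names(fx)[g_row])][1]
  gm_row <- grep("^group.*:month$", names(fx))[1]
  gl_row <- grep("^group.*:latency_days$", names(fx))[1]
  profile <- do.call(rbind, lapply(latency_grid_months, function(lm_) {
    ld <- months_to_days(lm_)
    l <- rep(0, length(fx))
    l[g_main] <- 1; l[gm_row] <- eval_month; l[gl_row] <- ld
    l[tw_row] <- eval_month * ld
    data.frame(latency_months = lm_, estimate = sum(l * fx),
               se = sqrt(drop(t(l) %*% vc %*% l)))
  }))
  threeway_p <- ct[grep("^group.*:month:latency_days$", rownames(ct)), "Pr(>|t|)"]
  structure(list(model = fit, coefficients = ct,
                 interaction_p = stats::setNames(
                   ct[grep("^group.*:month$", rownames(ct)), "Pr(>|t|)"],
                   rownames(ct)[grep("^group.*:month$", rownames(ct))]),
                 threeway_p = threeway_p,
                 latency_profile = profile,
                 group_difference = c(estimate = profile$estimate[which.min(
                   abs(profile$latency_months - stats::median(latency_grid_months)))],
                   se = NA, month = eval_month),
                 prediction_grid = NULL,
                 singular_fallback = fw$singular_fallback,
                 knots = knots),
            class = "decline_fit")
}
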