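# Matched-pair machinery: k-nearest historical controls per treated patient
# (Mahalanobis distance, greedy without replacement), TOST equivalence
# validation of the matching covariates, the Yang-Zhou short-/long-term
# hazard-ratio (YP) model for arms with possibly crossing hazards, and the
# repeated 9-of-k subsample bootstrap comparison.

#' Match k nearest historical controls to each treated patient
#'
#' Mahalanobis distance on covariates standardized by the control pool;
#' greedy assignment without replacement across treated patients, in a
#' seeded randomized treated order (so no treated patient is systematically
#' favoured). Ties are broken by control identifier.
#'
#' @param treated,controls patient tables containing `patient_id` and the
#'   matching covariates.
#' @param covariates covariate column names used for matching.
#' @param k number of controls per treated patient.
#' @param seed seed for the randomized treated order.
#' @return data frame of class `matched_sets`: `treated_id`, `control_id`,
#'   `rank` (1..k), `distance`.
#' @export
match_controls <- function(treated, controls,
                           covariates = c("age", "baseline_alsfrs"),
                           k = 10L, seed = 1L) {
  k <- check_count(k, "k")
  need <- k * nrow(treated)
  if (nrow(controls) < need) {
    stop(sprintf("control pool too small: %d controls available, %d required (k = %d x %d treated)",
                 nrow(controls), need, k, nrow(treated)), call. = FALSE)
  }
  xt <- as.matrix(treated[, covariates, drop = FALSE])
  xc <- as.matrix(controls[, covariates, drop = FALSE])
  ctr <- colMeans(xc); scl <- apply(xc, 2, stats::sd)
  scl[scl == 0] <- 1
  zt <- scale(xt, ctr, scl); zc <- scale(xc, ctr, scl)
  S <- stats::cov(zc)
  Sinv <- solve(S + diag(1e-10, ncol(S)))
  # full treated x control squared-distance matrix
  d2 <- outer(rowSums((zt %*% Sinv) * zt), rowSums((zc %*% Sinv) * zc), "+") -
    2 * (zt %*% Sinv %*% t(zc))
  d2[d2 < 0] <- 0
  ord <- with_seed(seed, sample.int(nrow(treated)))
  available <- rep(TRUE, nrow(controls))
  out <- vector("list", nrow(treated))
  for (i in ord) {
    di <- d2[i, ]
    di[!available] <- Inf
    pick <- order(di, controls$patient_id)[seq_len(k)]
    available[pick] <- FALSE
    out[[i]] <- data.frame(treated_id = treated$patient_id[i],
                           control_id = controls$patient_id[pick],
                           rank = seq_len(k),
                           distance = sqrt(di[pick]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("matched_sets", class(res))
  attr(res, "covariates") <- covariates
  attr(res, "k") <- k
  res
}

#' Two one-sided tests (TOST) for equivalence of two samples
#'
#' Welch two-sample TOST: equivalence within `+/- margin` is declared when
#' both one-sided tests reject at `alpha`. When both arms are constant and
#' equal the test is degenerate and passes with `degenerate = TRUE`.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param margin equivalence margin (> 0), on the scale of the values.
#' @param alpha one-sided significance level.
#' @return list: `pass`, `p_lower`, `p_upper`, `estimate` (mean difference),
#'   `margin`, `degenerate`.
#' @export
tost_equivalence <- function(x, y, margin, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per arm", call. = FALSE)
  check_pos(margin, "margin")
  diff <- mean(x) - mean(y)
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (se == 0) {
    pass <- abs(diff) < margin
    return(list(pass = pass, p_lower = as.numeric(!pass), p_upper = as.numeric(!pass),
                estimate = diff, margin = margin, degenerate = TRUE))
  }
  df <- se^4 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                  (stats::var(y) / length(y))^2 / (length(y) - 1))
  p_lower <- stats::pt((diff + margin) / se, df, lower.tail = FALSE) # H0: diff <= -margin
  p_upper <- stats::pt((diff - margin) / se, df, lower.tail = TRUE)  # H0: diff >= +margin
  list(pass = max(p_lower, p_upper) < alpha, p_lower = p_lower,
       p_upper = p_upper, estimate = diff, margin = margin, degenerate = FALSE)
}

# Risk-set table at distinct event times for a two-arm sample.
yp_risk_table <- function(time, event, g1) {
  ut <- sort(unique(time))
  idx <- match(time, ut)
  cnt_all <- tabulate(idx, nbins = length(ut))
  cnt_g1 <- tabulate(idx[g1], nbins = length(ut))
  ev_all <- tabulate(idx[event], nbins = length(ut))
  ev_g1 <- tabulate(idx[event & g1], nbins = length(ut))
  n_at <- rev(cumsum(rev(cnt_all)))
  n1_at <- rev(cumsum(rev(cnt_g1)))
  keep <- ev_all > 0
  nj <- n_at[keep]; n1j <- n1_at[keep]
  dj <- ev_all[keep]; d1j <- ev_g1[keep]
  # left-continuous pooled Kaplan-Meier at each event time
  s_minus <- c(1, cumprod(1 - dj / nj))[seq_len(sum(keep))]
  list(nj = nj, n1j = n1j, dj = dj, d1j = d1j, s_minus = s_minus)
}

yp_loglik <- function(b, rt) {
  th1 <- exp(b[1]); th2 <- exp(b[2])
  r <- th1 * th2 / (th1 + (th2 - th1) * rt$s_minus)
  n0j <- rt$nj - rt$n1j
  sum(rt$d1j * log(r) - rt$dj * log(n0j + rt$n1j * r))
}

yp_score_stat <- function(rt) {
  pj <- rt$n1j / rt$nj
  resid <- rt$d1j - rt$dj * pj
  vj <- ifelse(rt$nj > 1, rt$dj * (rt$nj - rt$dj) / (rt$nj - 1) * pj * (1 - pj), 0)
  w1 <- rt$s_minus; w2 <- 1 - rt$s_minus
  u <- c(sum(w1 * resid), sum(w2 * resid))
  V <- matrix(c(sum(w1^2 * vj), sum(w1 * w2 * vj),
                sum(w1 * w2 * vj), sum(w2^2 * vj)), 2, 2)
  qr_v <- qr(V)
  if (qr_v$rank < 2) {
    v11 <- V[1, 1]
    if (v11 <= 0) return(list(stat = 0, df = 1L))
    return(list(stat = u[1]^2 / v11, df = 1L))
  }
  list(stat = drop(t(u) %*% solve(V, u)), df = 2L)
}

#' Yang-Zhou short-/long-term hazard ratio (YP) model for two arms
#'
#' Fits the two-parameter model whose treated-over-control hazard ratio moves
#' from a short-term value `theta1` (at time 0) to a long-term value `theta2`
#' (in the tail) along the pooled baseline survival: `HR(t) =
#' theta1 * theta2 / (theta1 + (theta2 - theta1) * S(t-))`. Point estimates
#' maximize the pseudo partial likelihood with the pooled left-continuous
#' Kaplan-Meier plugged in for `S`; proportional hazards is the submodel
#' `theta1 = theta2`. The two-sided test of the joint null (both ratios 1) is
#' a 2-df score test whose components are weighted log-rank statistics with
#' predictable weights `S(t-)` and `1 - S(t-)`; below `perm_threshold`
#' subjects per arm a label-permutation p-value is used instead.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor/vector; the first level is the control arm.
#' @param perm_threshold minimum per-arm size for the asymptotic test.
#' @param n_perm permutations for the small-sample fallback.
#' @param seed seed for the permutation fallback.
#' @return list of class `yp_fit`: `short_term_hr`, `long_term_hr`,
#'   `statistic`, `df`, `p_value`, `method`, `converged`.
#' @references Yang, S. and Zhou, R. (2005). Semiparametric analysis of
#'   short-term and long-term hazard ratios. Biometrika.
#' @export
yp_fit <- function(time, event, group, perm_threshold = 30L, n_perm = 500L,
                   seed = 1L) {
  check_surv_input(time, event)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two arms are required", call. = FALSE)
  event <- as.logical(event)
  g1 <- group == levels(group)[2]
  if (sum(event & g1) < 1L || sum(event & !g1) < 1L) {
    stop("each arm needs at least one event", call. = FALSE)
  }
  rt <- yp_risk_table(time, event, g1)
  opt <- stats::optim(c(0, 0), function(b) -yp_loglik(b, rt), method = "BFGS",
                      control = list(maxit = 200))
  sc <- yp_score_stat(rt)
  if (min(sum(g1), sum(!g1)) < perm_threshold) {
    obs <- sc$stat
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      gp <- sample(g1)
      yp_score_stat(yp_risk_table(time, event, gp))$stat
    }, numeric(1)))
    p <- (1 + sum(perm >= obs)) / (n_perm + 1)
    method <- "permutation score test"
  } else {
    p <- stats::pchisq(sc$stat, sc$df, lower.tail = FALSE)
    method <- "asymptotic score test"
  }
  structure(list(short_term_hr = exp(opt$par[1]), long_term_hr = exp(opt$par[2]),
                 statistic = sc$stat, df = sc$df, p_value = p, method = method,
                 converged = opt$convergence == 0),
            class = "yp_fit")
}

#' @export
print.yp_fit <- function(x, ...) {
  cat(sprintf("YP model: short-term HR %.3f, long-term HR %.3f\n",
              x$short_term_hr, x$long_term_hr))
  cat(sprintf("  joint test: chisq = %.3f (%d df), p = %.4g [%s]\n",
              x$statistic, x$df, x$p_value, x$method))
  invisible(x)
}

# Kaplan-Meier median without the survfit overhead (used per bootstrap draw).
km_median_quick <- function(time, event) {
  rt <- yp_risk_table(time, event, rep(FALSE, length(time)))
  if (!length(rt$dj)) return(NA_real_)
  s <- cumprod(1 - rt$dj / rt$nj)
  tt <- sort(unique(time[event]))
  i <- which(s <= 0.5 + 1e-12)
  if (!length(i)) return(NA_real_)
  tt[i[1]]
}

#' Matched-pair bootstrap survival comparison
#'
#' For each draw, `subsample` of the `k` matched controls of every treated
#' patient are sampled, per-arm Kaplan-Meier medians are computed, and the
#' arms are compared with [yp_fit()]. Aggregates follow the
#' mean-of-the-medians convention.
#'
#' @param matched a `matched_sets` table from [match_controls()].
#' @param treated,controls patient tables with `patient_id`, `survival_days`,
#'   `event`.
#' @param draws number of bootstrap draws (>= 1).
#' @param subsample controls drawn per treated patient each draw.
#' @param seed integer seed; identical inputs and seed reproduce the result.
#' @return object of class `bootstrap_result`: per-draw table (`draw`,
#'   `median_treated`, `median_control`, `p`), `mean_of_medians`,
#'   `median_p`, `p_range`, `draws`.
#' @export
bootstrap_compare <- function(matched, treated, controls, draws = 1000L,
                              subsample = 9L, seed = 1L) {
  draws <- check_count(draws, "draws")
  subsample <- check_count(subsample, "subsample")
  k <- attr(matched, "k")
  if (!is.null(k) && subsample > k) {
    stop("`subsample` cannot exceed the matched-set size k", call. = FALSE)
  }
  sets <- split(matched$control_id, matched$treated_id)
  trt_time <- treated$survival_days
  trt_event <- as.logical(treated$event)
  ctl_idx <- lapply(sets, function(ids) match(ids, controls$patient_id))
  res <- with_seed(seed, {
    out <- matrix(NA_real_, draws, 3)
    for (b in seq_len(draws)) {
      pick <- unlist(lapply(ctl_idx, function(ix) ix[sample.int(length(ix), subsample)]),
                     use.names = FALSE)
      ct <- controls$survival_days[pick]
      ce <- as.logical(controls$event[pick])
      grp <- rep(c("control", "treated"), c(length(ct), length(trt_time)))
      p <- tryCatch(
        yp_fit(c(ct, trt_time), c(ce, trt_event),
               factor(grp, levels = c("control", "treated")),
               perm_threshold = 0L)$p_value,
        error = function(e) NA_real_)
      out[b, ] <- c(km_median_quick(trt_time, trt_event),
                    km_median_quick(ct, ce), p)
    }
    out
  })
  per_draw <- data.frame(draw = seq_len(draws), median_treated = res[, 1],
                         median_control = res[, 2], p = res[, 3])
  structure(list(per_draw = per_draw,
                 mean_of_medians = c(treated = mean(res[, 1], na.rm = TRUE),
                                     control = mean(res[, 2], na.rm = TRUE)),
                 median_p = stats::median(res[, 3], na.rm = TRUE),
                 p_range = range(res[, 3], na.rm = TRUE),
                 draws = draws, subsample = subsample),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Matched-pair bootstrap: %d draws, %d-of-k subsample\n",
              x$draws, x$subsample))
  cat(sprintf("  mean of medians: treated %.1f d, control %.1f d\n",
              x$mean_of_medians["treated"], x$mean_of_medians["control"]))
  cat(sprintf("  YP test p: median %.4g (range %.4g-%.4g)\n",
              x$median_p, x$p_range[1], x$p_range[2]))
  invisible(x)
}
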