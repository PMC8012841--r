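# Multimodal biomarker signature: baseline-anchored cytokine areas, non-linear
# PCA with optimal scaling and iterative missing-data imputation, loading
# thresholding, PC-score group tests, meta-PC construction and ROC evaluation.

#' Baseline-anchored signed area under a biomarker time course
#'
#' Trapezoidal signed area of `value - baseline` over the polyline through
#' `(0, baseline)` and the available follow-up points, in concentration x
#' months. Missing intermediate timepoints are bridged by connecting the
#' available neighbours; with no follow-up at all the area is undefined
#' (`NA`).
#'
#' @param baseline the pre-treatment value (the lower border of the area).
#' @param values follow-up values, one per element of `months` (`NA` allowed).
#' @param months follow-up months (default 3, 6, 9).
#' @return signed area, or `NA` when no follow-up value is present.
#' @examples
#' cytokine_auc(10, c(20, 20, 20))       # 75
#' cytokine_auc(10, c(20, NA, 20))       # still 75: single [3, 9] trapezoid
#' @export
cytokine_auc <- function(baseline, values, months = c(3, 6, 9)) {
  if (is.na(baseline)) return(NA_real_)
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  x <- c(0, months[ok])
  y <- c(0, values[ok] - baseline)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Group comparison of per-patient biomarker areas
#'
#' Rank-sum (default) or Welch t comparison of [cytokine_auc()] areas between
#' responders and non-responders, one test per variable; variables whose
#' groups are degenerate (fewer than 2 defined areas) are skipped with a log
#' entry. Following the reporting convention for these panels, variables are
#' flagged at p < 0.1.
#'
#' @param areas data frame `patient_id`, `variable`, `area`.
#' @param labels `responder_labels` table (or data frame `patient_id`,
#'   `label`).
#' @param test `"ranksum"` or `"ttest"`.
#' @param flag_level p-value below which a variable is flagged.
#' @return data frame `variable`, `n_responder`, `n_nonresponder`, `p`,
#'   `flagged`, with a `skipped` attribute naming untestable variables.
#' @export
auc_group_test <- function(areas, labels, test = c("ranksum", "ttest"),
                           flag_level = 0.1) {
  test <- match.arg(test)
  all_vars <- unique(areas$variable)
  lab <- labels$label[match(areas$patient_id, labels$patient_id)]
  areas <- areas[lab %in% c("responder", "non-responder") & !is.na(areas$area), ]
  lab <- labels$label[match(areas$patient_id, labels$patient_id)]
  rows <- lapply(split(seq_len(nrow(areas)), areas$variable), function(ix) {
    a <- areas$area[ix]; g <- droplevels(factor(lab[ix]))
    n_r <- sum(g == "responder"); n_n <- sum(g == "non-responder")
    if (n_r < 2L || n_n < 2L) return(NULL)
    p <- if (test == "ranksum") {
      suppressWarnings(stats::wilcox.test(a ~ g)$p.value)
    } else {
      stats::t.test(a ~ g)$p.value
    }
    data.frame(variable = areas$variable[ix[1]], n_responder = n_r,
               n_nonresponder = n_n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(variable = character(0), n_responder = integer(0),
                      n_nonresponder = integer(0), p = numeric(0))
  }
  out$flagged <- out$p < flag_level
  rownames(out) <- NULL
  attr(out, "skipped") <- setdiff(all_vars, out$variable)
  out
}

# one optimal-scaling pass for an ordinal column: monotone (isotonic)
# quantification of the category values against the current reconstruction
optimal_scale_ordinal <- function(codes, target) {
  obs <- !is.na(codes)
  lev <- sort(unique(codes[obs]))
  m <- vapply(lev, function(l) mean(target[obs][codes[obs] == l]), numeric(1))
  w <- vapply(lev, function(l) sum(codes[obs] == l), numeric(1))
  # weighted pool-adjacent-violators over the ordered categories
  val <- m; wt <- w; idx <- as.list(seq_along(lev))
  i <- 1L
  while (i < length(val)) {
    if (val[i] > val[i + 1L] + 1e-12) {
      val[i] <- (wt[i] * val[i] + wt[i + 1L] * val[i + 1L]) / (wt[i] + wt[i + 1L])
      wt[i] <- wt[i] + wt[i + 1L]
      idx[[i]] <- c(idx[[i]], idx[[i + 1L]])
      val <- val[-(i + 1L)]; wt <- wt[-(i + 1L)]; idx <- idx[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  q <- numeric(length(lev))
  for (b in seq_along(val)) q[idx[[b]]] <- val[b]
  q[match(codes, lev)]
}

#' Non-linear principal component analysis with optimal scaling
#'
#' Alternating-least-squares PCA that handles mixed scalar/ordinal variables
#' and missing entries: scalars are standardized; ordinal variables are
#' replaced by monotone optimal-scaling quantifications re-estimated each
#' cycle; missing entries start at the variable mean and are re-imputed from
#' the current low-rank reconstruction each cycle. Convergence is declared
#' when the change in mean squared reconstruction error over observed entries
#' falls below `tol`. On complete all-scalar data the result coincides with
#' classical PCA of the correlation matrix.
#'
#' Components are sign-oriented so that each component's largest-|loading|
#' variable loads positively. Loadings are variable-component correlations;
#' scores are normalized to mean 0, sd 1; `vaf` is the percent variance
#' accounted for.
#'
#' @param x numeric matrix or data frame (patients x variables); ordinal
#'   variables coded as integers.
#' @param types character vector per variable, `"scalar"` or `"ordinal"`
#'   (default all scalar).
#' @param n_components number of components (< min(dim)).
#' @param tol convergence tolerance on the reconstruction error.
#' @param max_iter maximum ALS cycles.
#' @return object of class `nlpca`: `loadings` (p x k, in \[-1, 1\]),
#'   `scores` (n x k, normalized), `vaf` (percent), `converged`,
#'   `iterations`, `dropped` (constant variables removed with a warning).
#' @export
nlpca_fit <- function(x, types = NULL, n_components = 3L, tol = 1e-6,
                      max_iter = 500L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(types)) types <- rep("scalar", ncol(x))
  if (length(types) != ncol(x)) stop("`types` must name every variable", call. = FALSE)
  n_components <- check_count(n_components, "n_components")
  # drop constant (or all-missing) variables
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sds) | sds == 0
  if (any(drop)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    types <- types[!drop]
    x <- x[, !drop, drop = FALSE]
  }
  n <- nrow(x); p <- ncol(x)
  if (p < 3L || n < 5L) stop("need at least 3 variables and 5 patients", call. = FALSE)
  if (n_components >= min(n, p)) {
    stop("`n_components` must be smaller than both dimensions", call. = FALSE)
  }
  obs <- !is.na(x)
  std <- function(v) {
    mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (v - mu) / s
  }
  z <- apply(x, 2, std)
  z[!obs] <- 0  # variable mean after standardization
  err_prev <- Inf; converged <- FALSE; iter <- 0L
  recon <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    sv <- svd(z, nu = n_components, nv = n_components)
    dvals <- sv$d[seq_len(n_components)]
    recon <- sv$u %*% (dvals * t(sv$v))
    # re-impute missing entries from the reconstruction
    z[!obs] <- recon[!obs]
    # optimal scaling of ordinal variables against the reconstruction
    for (j in which(types == "ordinal")) {
      q <- optimal_scale_ordinal(x[, j], recon[, j])
      zj <- z[, j]
      zj[obs[, j]] <- q[obs[, j]]
      z[, j] <- std(zj)
      z[is.na(z[, j]), j] <- recon[is.na(z[, j]), j]
    }
    # keep every column centred/scaled after imputation drift
    z <- apply(z, 2, std)
    err <- mean((z[obs] - recon[obs])^2)
    if (is.finite(err_prev) && abs(err_prev - err) < tol) { converged <- TRUE; break }
    err_prev <- err
  }
  if (!converged) {
    warning("NLPCA did not converge in ", max_iter, " cycles; returning best iterate")
  }
  sv <- svd(z, nu = n_components, nv = n_components)
  dvals <- sv$d[seq_len(n_components)]
  scores <- sv$u * sqrt(n)                      # mean ~0, sd ~1 by orthonormality
  scores <- apply(scores, 2, function(s) (s - mean(s)) / stats::sd(s))
  loadings <- stats::cor(z, scores)
  # sign convention: largest-|loading| variable of each component positive
  for (k in seq_len(n_components)) {
    jmax <- which.max(abs(loadings[, k]))
    if (loadings[jmax, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  vaf <- 100 * dvals^2 / sum(sv$d^2)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  structure(list(loadings = loadings, scores = scores, vaf = vaf,
                 converged = converged, iterations = iter,
                 dropped = if (any(drop)) colnames(x)[drop] else character(0),
                 n = n, p = p),
            class = "nlpca")
}

#' @export
print.nlpca <- function(x, ...) {
  cat(sprintf("NLPCA: %d patients x %d variables, %d components (%s in %d cycles)\n",
              x$n, x$p, ncol(x$loadings),
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("  variance accounted for (%):", paste(sprintf("%.1f", x$vaf), collapse = ", "), "\n")
  invisible(x)
}

#' Retain variables over an absolute loading threshold
#'
#' Variables whose |loading| on the chosen component strictly exceeds
#' `cutoff` ("over 0.5" read strictly), preserving sign. Empty retention is
#' allowed.
#'
#' @param pca an `nlpca` object (or any matrix-like `loadings`).
#' @param component component index.
#' @param cutoff absolute loading threshold in \[0, 1).
#' @return named numeric vector of retained loadings.
#' @export
threshold_loadings <- function(pca, component = 1L, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff >= 1) {
    stop("invalid `cutoff`: must be in [0, 1)", call. = FALSE)
  }
  L <- if (inherits(pca, "nlpca")) pca$loadings else as.matrix(pca)
  l <- L[, component]
  l[abs(l) > cutoff]
}

#' Group test of principal-component scores by responder status
#'
#' With repeated timepoints, a linear mixed model of the score on the
#' responder category with a per-patient random intercept; with a single
#' timepoint this degrades to a pooled two-sample t test (the mixed model's
#' degenerate case).
#'
#' @param scores data frame `patient_id`, `timepoint`, `score` (timepoint may
#'   be constant).
#' @param labels `responder_labels` table or data frame `patient_id`,
#'   `label`.
#' @param alpha significance level for the `significant` flag.
#' @return list: `p_value`, `estimate` (responder minus non-responder),
#'   `significant`, `method`.
#' @export
pc_group_test <- function(scores, labels, alpha = 0.05) {
  d <- scores
  d$label <- labels$label[match(d$patient_id, labels$patient_id)]
  d <- d[d$label %in% c("responder", "non-responder") & !is.na(d$score), ]
  d$label <- factor(as.character(d$label), levels = c("non-responder", "responder"))
  if (nlevels(droplevels(d$label)) < 2L) {
    return(list(p_value = NA_real_, estimate = NA_real_, significant = FALSE,
                method = "untestable (one group)"))
  }
  multi_tp <- length(unique(d$timepoint)) > 1L &&
    any(table(d$patient_id) > 1L)
  if (multi_tp) {
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lmerTest::lmer(score ~ label + (1 | patient_id), data = d))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ct <- stats::coef(summary(fit))
      return(list(p_value = ct["labelresponder", "Pr(>|t|)"],
                  estimate = ct["labelresponder", "Estimate"],
                  significant = ct["labelresponder", "Pr(>|t|)"] < alpha,
                  method = "linear mixed model"))
    }
  }
  tt <- stats::t.test(score ~ label, data = d, var.equal = TRUE)
  est <- unname(tt$estimate["mean in group responder"] -
                  tt$estimate["mean in group non-responder"])
  list(p_value = tt$p.value, estimate = est,
       significant = tt$p.value < alpha, method = "two-sample t test")
}

#' Build a meta principal component from significant PC scores
#'
#' First principal component of the patient-by-significant-PC score matrix
#' (columns standardized; missing scores mean-imputed with a logged count),
#' sign-oriented so that responders have the higher mean meta score. With no
#' significant PCs an explicit empty signature is returned instead of an
#' error.
#'
#' @param score_matrix numeric matrix, patients x significant PCs, with
#'   patient identifiers as rownames.
#' @param labels `responder_labels` table used only for sign orientation.
#' @return object of class `meta_pc`: `scores` (named vector), `weights`,
#'   `components` (contributing column names), `n_imputed`, `empty`.
#' @export
build_meta_pc <- function(score_matrix, labels) {
  if (is.null(score_matrix) || ncol(as.matrix(score_matrix)) == 0L) {
    return(structure(list(scores = NULL, weights = NULL, components = character(0),
                          n_imputed = 0L, empty = TRUE), class = "meta_pc"))
  }
  m <- as.matrix(score_matrix)
  n_imputed <- sum(is.na(m))
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  z <- scale(m)
  z[is.nan(z)] <- 0
  if (ncol(m) == 1L) {
    meta <- drop(z)
    w <- stats::setNames(1, colnames(m))
  } else {
    sv <- svd(z, nu = 1, nv = 1)
    meta <- drop(z %*% sv$v[, 1])
    w <- stats::setNames(drop(sv$v[, 1]), colnames(m))
  }
  meta <- (meta - mean(meta)) / stats::sd(meta)
  names(meta) <- rownames(m)
  lab <- labels$label[match(rownames(m), labels$patient_id)]
  mr <- mean(meta[lab %in% "responder"])
  mn <- mean(meta[lab %in% "non-responder"])
  if (is.finite(mr) && is.finite(mn) && mr < mn) {
    meta <- -meta; w <- -w
  }
  structure(list(scores = meta, weights = w, components = colnames(m),
                 n_imputed = n_imputed, empty = FALSE),
            class = "meta_pc")
}

#' ROC evaluation of a score against responder labels
#'
#' The area under the ROC curve via the rank (Mann-Whitney) formulation, with
#' a seeded label-permutation p-value (one-sided: is the observed AUC larger
#' than under exchangeable labels?).
#'
#' @param scores numeric scores (higher = more responder-like).
#' @param labels logical or factor: `TRUE`/"responder" = positive class.
#' @param n_perm number of label permutations.
#' @param seed permutation seed.
#' @return object of class `roc_result`: `auc`, `p_value`, `perm_q95` (95th
#'   percentile of the permutation-null AUC), `curve` (data frame
#'   `threshold`, `sensitivity`, `specificity`), `n_positive`, `n_negative`,
#'   `n_perm`.
#' @export
roc_evaluate <- function(scores, labels, n_perm = 10000L, seed = 1L) {
  pos <- if (is.logical(labels)) labels else labels %in% c("responder", "TRUE")
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  auc_rank <- function(s, y1) {
    r <- rank(s)
    (sum(r[y1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_rank(scores, pos)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    auc_rank(scores, sample(pos))
  }, numeric(1)))
  p <- (1 + sum(perm >= auc)) / (n_perm + 1)
  perm_q95 <- unname(stats::quantile(perm, 0.95, type = 7))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(th, function(t) mean(scores[!pos] < t), numeric(1))
  structure(list(auc = auc, p_value = p, perm_q95 = perm_q95,
                 curve = data.frame(threshold = th, sensitivity = sens,
                                    specificity = spec),
                 n_positive = n1, n_negative = n0, n_perm = n_perm),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (permutation p = %.4g; %d vs %d patients)\n",
              x$auc, x$p_value, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# average panels over the analysis window (months in (0, window]) per package
pool_panel_window <- function(panels, window) {
  tps <- as.numeric(sub("^t", "", names(panels)))
  use <- which(tps > 0 & tps <= window)
  if (!length(use)) return(NULL)
  ids <- unique(unlist(lapply(panels[use], function(p) p$patient_id)))
  vars <- setdiff(colnames(panels[[use[1]]]), "patient_id")
  acc <- matrix(0, length(ids), length(vars), dimnames = list(ids, vars))
  cnt <- matrix(0L, length(ids), length(vars), dimnames = list(ids, vars))
  for (u in use) {
    p <- panels[[u]]
    m <- as.matrix(p[, vars, drop = FALSE])
    rows <- match(p$patient_id, ids)
    o <- !is.na(m)
    m[!o] <- 0
    acc[rows, ] <- acc[rows, ] + m
    cnt[rows, ] <- cnt[rows, ] + o
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  out
}

#' Run the biomarker-signature stage
#'
#' For each analysis window (months), pools each biomarker package over its
#' available timepoints in the window, fits [nlpca_fit()] per package, tests
#' every PC's scores between responder groups, collects the significant PCs
#' into a meta-PC ([build_meta_pc()]) and evaluates it by permutation-tested
#' ROC ([roc_evaluate()]). Packages with no data in a window are tolerated
#' and skipped.
#'
#' @param panel_sets named list of package panel lists (each as returned by
#'   [generate_biomarkers()]).
#' @param types_list optional named list of per-package `types` vectors for
#'   [nlpca_fit()].
#' @param labels `responder_labels` table.
#' @param windows analysis windows in months.
#' @param n_components components per package.
#' @param loading_cutoff threshold for the retained-variable lists.
#' @param alpha significance level for PC selection.
#' @param n_perm,seed ROC permutation settings.
#' @return list of class `signature_result` with one entry per window:
#'   `pc_tests` table, per-package `nlpca` fits, `retained` loading lists,
#'   `meta` ([build_meta_pc()]) and `roc` ([roc_evaluate()]; `NULL` when the
#'   signature is empty).
#' @export
run_signature <- function(panel_sets, labels, types_list = NULL,
                          windows = c(3, 6, 12), n_components = 3L,
                          loading_cutoff = 0.5, alpha = 0.05,
                          n_perm = 2000L, seed = 1L) {
  out <- list()
  for (w in windows) {
    fits <- list(); tests <- list(); retained <- list()
    score_cols <- list()
    for (pkg in names(panel_sets)) {
      pooled <- pool_panel_window(panel_sets[[pkg]], w)
      if (is.null(pooled)) next
      types <- if (!is.null(types_list)) types_list[[pkg]] else NULL
      fit <- tryCatch(nlpca_fit(pooled, types = types, n_components = n_components),
                      error = function(e) NULL)
      if (is.null(fit)) next
      fits[[pkg]] <- fit
      for (k in seq_len(ncol(fit$scores))) {
        pc_id <- sprintf("%s_PC%d_w%g", pkg, k, w)
        sc <- data.frame(patient_id = rownames(fit$scores), timepoint = w,
                         score = fit$scores[, k], stringsAsFactors = FALSE)
        tst <- pc_group_test(sc, labels, alpha = alpha)
        tests[[pc_id]] <- data.frame(window = w, package = pkg, component = k,
                                     vaf = fit$vaf[k], p = tst$p_value,
                                     estimate = tst$estimate,
                                     significant = isTRUE(tst$significant),
                                     stringsAsFactors = FALSE)
        retained[[pc_id]] <- threshold_loadings(fit, k, loading_cutoff)
        if (isTRUE(tst$significant)) {
          score_cols[[pc_id]] <- stats::setNames(fit$scores[, k], rownames(fit$scores))
        }
      }
    }
    pc_tests <- do.call(rbind, tests)
    rownames(pc_tests) <- NULL
    meta <- if (length(score_cols)) {
      ids <- sort(unique(unlist(lapply(score_cols, names))))
      m <- sapply(score_cols, function(s) s[ids])
      rownames(m) <- ids
      build_meta_pc(m, labels)
    } else {
      build_meta_pc(NULL, labels)
    }
    roc <- NULL
    if (!meta$empty) {
      lab <- labels$label[match(names(meta$scores), labels$patient_id)]
      use <- lab %in% c("responder", "non-responder")
      if (length(unique(lab[use])) == 2L) {
        roc <- roc_evaluate(meta$scores[use], lab[use] == "responder",
                            n_perm = n_perm, seed = seed)
      }
    }
    out[[paste0("w", w)]] <- list(window = w, fits = fits, pc_tests = pc_tests,
                                  retained = retained, meta = meta, roc = roc)
  }
  class(out) <- "signature_result"
  out
}
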