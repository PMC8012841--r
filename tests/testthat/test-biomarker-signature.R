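# Cytokine areas, NLPCA, loading thresholds, PC group tests, meta-PC and ROC.

test_that("the baseline-anchored area matches the trapezoid oracle", {
  expect_equal(cytokine_auc(10, c(10, 10, 10)), 0)
  expect_equal(cytokine_auc(10, c(20, 20, 20)), 75)       # 15 + 30 + 30
  expect_equal(cytokine_auc(10, c(20, NA, 20)), 75)       # 15 + one [3,9] trapezoid
  expect_true(is.na(cytokine_auc(10, c(NA, NA, NA))))
  expect_true(is.na(cytokine_auc(NA, c(1, 2, 3))))
})

test_that("the area is linear in scale and invariant to common shifts", {
  set.seed(91)
  for (i in 1:20) {
    b <- runif(1, 5, 20); v <- runif(3, 0, 40); cc <- runif(1, 0.5, 3)
    a <- cytokine_auc(b, v)
    expect_equal(cytokine_auc(cc * b, cc * v), cc * a, tolerance = 1e-10)
    expect_equal(cytokine_auc(b + 7, v + 7), a, tolerance = 1e-10)
  }
})

fake_labels <- function(ids, lab) {
  data.frame(patient_id = ids, label = factor(lab,
    levels = c("responder", "non-responder", "non-assignable")))
}

test_that("area group tests flag separated variables and skip degenerate ones", {
  set.seed(92)
  ids <- sprintf("P%02d", 1:30)
  lab <- fake_labels(ids, rep(c("responder", "non-responder"), each = 15))
  areas <- rbind(
    data.frame(patient_id = ids, variable = "sep",
               area = c(rnorm(15, 0), rnorm(15, 30, 0.5))),
    data.frame(patient_id = ids, variable = "null", area = rnorm(30)),
    data.frame(patient_id = ids, variable = "gone", area = NA_real_))
  res <- auc_group_test(areas, lab)
  expect_lt(res$p[res$variable == "sep"], 0.01)
  expect_true(res$flagged[res$variable == "sep"])
  expect_true("gone" %in% attr(res, "skipped"))
})

test_that("a shifted inflammatory factor is recovered by the area tests", {
  hits <- 0
  for (s in 1:10) {
    trt <- generate_treated_cohort(treated_spec_36(seed = 900 + s))
    specs <- default_biomarker_specs()
    sp <- specs$cytokines; sp$seed <- 950 + s
    pan <- generate_biomarkers(trt$patients, sp, trt$latent)
    lab <- fake_labels(trt$latent$patient_id,
                       ifelse(trt$latent$latent_responder, "responder", "non-responder"))
    ids <- pan$t0$patient_id
    areas <- do.call(rbind, lapply(setdiff(names(pan$t0), "patient_id"), function(v) {
      vals <- sapply(c(3, 6, 9), function(m) pan[[paste0("t", m)]][[v]][match(ids, pan[[paste0("t", m)]]$patient_id)])
      data.frame(patient_id = ids, variable = v,
                 area = vapply(seq_along(ids), function(i)
                   cytokine_auc(pan$t0[[v]][i], vals[i, ]), numeric(1)))
    }))
    res <- auc_group_test(areas, lab)
    # the truly shifted set loads on the inflammatory factor (first 6 vars)
    shifted <- rownames(specs$cytokines$loading_matrix)[1:6]
    hits <- hits + all(shifted %in% res$variable[res$flagged])
  }
  expect_gte(hits, 7)
})

test_that("NLPCA equals classical PCA on complete scalar data", {
  set.seed(93)
  x <- matrix(rnorm(150 * 8), 150, 8) %*% matrix(rnorm(64), 8, 8)
  fit <- nlpca_fit(x, n_components = 3)
  ev <- eigen(cor(x))
  classical <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  for (k in 1:3) {
    expect_gt(tucker_congruence(fit$loadings[, k], classical[, k]), 0.999)
  }
  expect_equal(fit$vaf[1:3], 100 * ev$values[1:3] / 8, tolerance = 1e-6)
  expect_true(all(abs(fit$loadings) <= 1 + 1e-8))
  # scores of distinct components are orthogonal
  expect_lt(max(abs(cor(fit$scores)[lower.tri(diag(3))])), 1e-6)
  # VAF ordered and bounded
  expect_true(all(diff(fit$vaf) <= 1e-9))
  expect_lte(sum(fit$vaf), 100 + 1e-9)
})

test_that("NLPCA recovers a two-factor structure despite 10% missingness", {
  set.seed(94)
  L <- matrix(0, 20, 2); L[1:12, 1] <- 0.85; L[13:20, 2] <- 0.65
  f <- matrix(rnorm(200 * 2), 200, 2)
  x <- f %*% t(L) + matrix(rnorm(200 * 20, 0, 0.4), 200, 20)
  x[matrix(runif(4000) < 0.1, 200, 20)] <- NA
  fit <- nlpca_fit(x, n_components = 2)
  expect_gt(tucker_congruence(fit$loadings[, 1], L[, 1]), 0.9)
  expect_gt(tucker_congruence(fit$loadings[, 2], L[, 2]), 0.9)
  expect_true(fit$converged)
})

test_that("a constant column is dropped with a warning and does not change the result", {
  set.seed(95)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("v", 1:5)
  xc <- cbind(x, flat = 1)
  expect_warning(fit2 <- nlpca_fit(xc, n_components = 2), "flat")
  fit1 <- nlpca_fit(x, n_components = 2)
  expect_equal(fit1$loadings, fit2$loadings, tolerance = 1e-8)
})

test_that("ordinal optimal scaling preserves monotone structure", {
  set.seed(96)
  f <- rnorm(300)
  x <- sapply(1:6, function(j) 0.8 * f + rnorm(300, 0, 0.5))
  colnames(x) <- paste0("v", 1:6)
  x[, 1] <- as.integer(cut(x[, 1], quantile(x[, 1], seq(0, 1, 0.2)),
                           include.lowest = TRUE))
  fit <- nlpca_fit(x, types = c("ordinal", rep("scalar", 5)), n_components = 2)
  expect_gt(abs(fit$loadings[1, 1]), 0.5)  # ordinal variable still loads on PC1
})

test_that("loading thresholding is strict and validated", {
  L <- matrix(c(0.6, -0.7, 0.4), 3, 1, dimnames = list(c("a", "b", "c"), "PC1"))
  kept <- threshold_loadings(L, 1, 0.5)
  expect_setequal(names(kept), c("a", "b"))
  expect_equal(unname(kept["b"]), -0.7)
  expect_length(threshold_loadings(matrix(0.5, 1, 1, dimnames = list("x", NULL)), 1, 0.5), 0)
  expect_length(threshold_loadings(L, 1, 0), 3)
  expect_error(threshold_loadings(L, 1, 1), "cutoff")
})

test_that("PC group test detects a 1.5 SD shift and degrades to a t test", {
  set.seed(97)
  ids <- sprintf("P%02d", 1:30)
  lab <- fake_labels(ids, rep(c("responder", "non-responder"), each = 15))
  hits <- 0
  for (i in 1:20) {
    sc <- data.frame(patient_id = ids, timepoint = 3,
                     score = rnorm(30) + 1.5 * rep(c(1, 0), each = 15))
    hits <- hits + (pc_group_test(sc, lab)$p_value < 0.05)
  }
  expect_gte(hits, 17)
  # single-timepoint equals the pooled t test exactly
  sc <- data.frame(patient_id = ids, timepoint = 3, score = rnorm(30))
  got <- pc_group_test(sc, lab)
  ora <- t.test(sc$score[16:30], sc$score[1:15], var.equal = TRUE)$p.value
  expect_equal(got$p_value, ora)
  expect_equal(got$method, "two-sample t test")
})

test_that("repeated timepoints engage the mixed model", {
  set.seed(98)
  ids <- sprintf("P%02d", 1:30)
  lab <- fake_labels(ids, rep(c("responder", "non-responder"), each = 15))
  sc <- do.call(rbind, lapply(c(3, 6, 12), function(tp) {
    data.frame(patient_id = ids, timepoint = tp,
               score = rnorm(30, sd = 0.5) + rep(c(1, 0), each = 15))
  }))
  got <- pc_group_test(sc, lab)
  expect_equal(got$method, "linear mixed model")
  expect_lt(got$p_value, 0.01)
  expect_gt(got$estimate, 0.5)
})

test_that("meta-PC reduces to its inputs in degenerate cases and aggregates signal", {
  set.seed(99)
  ids <- sprintf("P%02d", 1:30)
  lab <- fake_labels(ids, rep(c("responder", "non-responder"), each = 15))
  s1 <- rnorm(30) + rep(c(1, 0), each = 15)
  m1 <- build_meta_pc(matrix(s1, dimnames = list(ids, "pc1")), lab)
  expect_gt(abs(cor(m1$scores, s1)), 0.999)
  # two perfectly correlated columns: meta proportional to either
  m2 <- build_meta_pc(matrix(c(s1, 2 * s1 + 3), ncol = 2,
                             dimnames = list(ids, c("a", "b"))), lab)
  expect_gt(abs(cor(m2$scores, s1)), 0.999)
  # orientation: responders higher
  expect_gt(mean(m2$scores[1:15]), mean(m2$scores[16:30]))
  # empty signature is explicit, not an exception
  m0 <- build_meta_pc(NULL, lab)
  expect_true(m0$empty)
  # aggregation: three noisy group-separating PCs beat the best single one
  # (independent-oracle win rate at this separation is about 0.96)
  wins <- 0
  for (i in 1:30) {
    ss <- sapply(1:3, function(k) rnorm(30, sd = 1) + rep(c(1.5, 0), each = 15))
    rownames(ss) <- ids
    meta <- build_meta_pc(ss, lab)$scores
    smd <- function(v) (mean(v[1:15]) - mean(v[16:30])) /
      sqrt((var(v[1:15]) + var(v[16:30])) / 2)
    wins <- wins + (smd(meta) >= max(apply(ss, 2, smd)))
  }
  expect_gte(wins, 21)  # >= 70% of seeds
})

test_that("ROC area follows the rank formulation exactly", {
  r <- roc_evaluate(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                    n_perm = 200, seed = 1)
  expect_equal(r$auc, 1)
  r2 <- roc_evaluate(rep(5, 10), rep(c(TRUE, FALSE), 5), n_perm = 200, seed = 1)
  expect_equal(r2$auc, 0.5)
  set.seed(100)
  for (i in 1:50) {
    s <- rnorm(24); y <- sample(c(TRUE, FALSE), 24, replace = TRUE,
                                prob = c(0.5, 0.5))
    if (!any(y) || all(y)) next
    got <- roc_evaluate(s, y, n_perm = 10, seed = 1)$auc
    u <- unname(wilcox.test(s[y], s[!y], exact = FALSE)$statistic)
    expect_equal(got, u / (sum(y) * sum(!y)))
    # invariance under strictly monotone transforms
    expect_equal(roc_evaluate(exp(s), y, n_perm = 10, seed = 1)$auc, got)
  }
  expect_error(roc_evaluate(1:5, rep(TRUE, 5)), "both classes")
})

test_that("permutation p-values are approximately uniform under random labels", {
  set.seed(101)
  p <- replicate(120, {
    s <- rnorm(30); y <- rep(c(TRUE, FALSE), 15)
    roc_evaluate(s, sample(y), n_perm = 400, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("the full signature stage finds the planted responder structure", {
  trt <- generate_treated_cohort(treated_spec_36(seed = 102))
  lab <- fake_labels(trt$latent$patient_id,
                     ifelse(trt$latent$latent_responder, "responder", "non-responder"))
  specs <- default_biomarker_specs()
  panels <- lapply(specs, function(sp) generate_biomarkers(trt$patients, sp, trt$latent))
  types <- lapply(specs, function(sp) {
    vars <- rownames(sp$loading_matrix)
    ifelse(vars %in% names(sp$ordinal_vars), "ordinal", "scalar")
  })
  sig <- run_signature(panels, lab, types_list = types, windows = c(3, 12),
                       n_perm = 500, seed = 103)
  w12 <- sig$w12
  expect_gt(sum(w12$pc_tests$significant), 0)
  expect_false(w12$meta$empty)
  expect_gt(w12$roc$auc, 0.7)
  expect_lt(w12$roc$p_value, 0.05)
  # imaging has no data before month 12 and is tolerated at the early window
  expect_false("imaging" %in% names(sig$w3$fits))
  expect_true("imaging" %in% names(w12$fits))
})
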