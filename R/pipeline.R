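# End-to-end orchestration: simulate -> survive -> match -> decline ->
# respond -> signature, with a YAML-style config, per-stage seeds, delimited
# artifacts and a JSON manifest of content hashes. Latent responder flags are
# quarantined under truth/ and never read by any analysis stage.

PIPELINE_STAGES <- c("simulate", "survive", "match", "decline", "respond", "signature")

#' Build a pipeline run configuration
#'
#' All tunables of the pipeline in one object: generator specifications,
#' classification thresholds, matching and bootstrap settings, analysis
#' windows and per-stage seeds (derived from one master seed so stages can be
#' re-run in isolation).
#'
#' @param seed master integer seed.
#' @param control a [cohort_spec()] for the historical-control arm.
#' @param treated a [treated_spec()].
#' @param trajectory a [trajectory_spec()].
#' @param biomarkers named list of [biomarker_spec()]s.
#' @param responder_band non-assignable band, days.
#' @param loading_cutoff absolute loading threshold.
#' @param alpha significance level.
#' @param tost_margin_sd TOST margin in pooled-SD units.
#' @param match_covariates covariates for [match_controls()].
#' @param k,subsample,draws matched-pair bootstrap settings.
#' @param slope_window_months visits up to this month feed the robust slope.
#' @param decline_max_month,decline_eval_month decline-model window.
#' @param signature_windows analysis windows (months).
#' @param n_perm ROC permutations.
#' @param stages stages enabled for [run_pipeline()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(seed = 20260101L,
                       control = cohort_spec(),
                       treated = treated_spec(),
                       trajectory = trajectory_spec(),
                       biomarkers = default_biomarker_specs(),
                       responder_band = 60,
                       loading_cutoff = 0.5,
                       alpha = 0.05,
                       tost_margin_sd = 0.5,
                       match_covariates = c("age", "baseline_alsfrs"),
                       k = 10L, subsample = 9L, draws = 500L,
                       slope_window_months = 3,
                       decline_max_month = 6, decline_eval_month = 6,
                       signature_windows = c(3, 6, 12),
                       n_perm = 2000L,
                       stages = PIPELINE_STAGES) {
  seed <- as.integer(seed) %% 2000000000L
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    seed = seed,
    seeds = stats::setNames(as.list((seed + 101L * seq_along(PIPELINE_STAGES)) %% 2000000000L),
                            PIPELINE_STAGES),
    control = control, treated = treated, trajectory = trajectory,
    biomarkers = biomarkers,
    thresholds = list(responder_band = responder_band,
                      loading_cutoff = loading_cutoff, alpha = alpha,
                      tost_margin_sd = tost_margin_sd),
    match = list(covariates = match_covariates, k = as.integer(k),
                 subsample = as.integer(subsample), draws = as.integer(draws)),
    slope_window_months = slope_window_months,
    decline = list(max_month = decline_max_month, eval_month = decline_eval_month),
    signature = list(windows = signature_windows, n_perm = as.integer(n_perm)),
    stages = stages
  ), class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys map 1:1 to [run_config()] arguments; `control`, `treated`
#' (with `base`), `trajectory` and `biomarkers` keys map to the corresponding
#' spec constructors.
#'
#' @param path YAML file.
#' @return a `run_config` object.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$control)) args$control <- do.call(cohort_spec, y$control)
  if (!is.null(y$treated)) {
    t <- y$treated
    if (!is.null(t$base)) t$base <- do.call(cohort_spec, t$base)
    args$treated <- do.call(treated_spec, t)
  }
  if (!is.null(y$trajectory)) args$trajectory <- do.call(trajectory_spec, y$trajectory)
  if (!is.null(y$biomarkers)) args$biomarkers <- do.call(default_biomarker_specs, y$biomarkers)
  for (k in c("seed", "responder_band", "loading_cutoff", "alpha",
              "tost_margin_sd", "match_covariates", "k", "subsample", "draws",
              "slope_window_months", "decline_max_month", "decline_eval_month",
              "signature_windows", "n_perm", "stages")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

stage_dir <- function(out_dir, stage) file.path(out_dir, stage)

require_artifact <- function(out_dir, stage, file) {
  p <- file.path(out_dir, stage, file)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s': enable the '%s' stage first", p, stage),
         call. = FALSE)
  }
  p
}

log_event <- function(log_path, ...) {
  rec <- list(...)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = log_path, append = TRUE)
}

stage_simulate <- function(config, out_dir) {
  d <- stage_dir(out_dir, "simulate")
  dir.create(file.path(d, "truth"), recursive = TRUE, showWarnings = FALSE)
  ctrl_spec <- config$control
  ctrl_spec$seed <- config$seeds$simulate
  trt_spec <- config$treated
  trt_spec$base$seed <- (config$seeds$simulate + 1L) %% 2000000000L
  ctrl <- generate_control_cohort(ctrl_spec)
  trt <- generate_treated_cohort(trt_spec)
  cv <- generate_trajectories(ctrl, config$trajectory,
                              seed = (config$seeds$simulate + 2L) %% 2000000000L)
  tv <- generate_trajectories(trt$patients, config$trajectory, trt$latent,
                              seed = (config$seeds$simulate + 3L) %% 2000000000L)
  write_table_csv(ctrl, file.path(d, "control_patients.csv"))
  write_table_csv(trt$patients, file.path(d, "treated_patients.csv"))
  write_table_csv(cv, file.path(d, "control_visits.csv"))
  write_table_csv(tv, file.path(d, "treated_visits.csv"))
  for (pkg in names(config$biomarkers)) {
    spec <- config$biomarkers[[pkg]]
    spec$seed <- (config$seeds$simulate + 10L + match(pkg, names(config$biomarkers))) %% 2000000000L
    panels <- generate_biomarkers(trt$patients, spec, trt$latent)
    long <- do.call(rbind, lapply(names(panels), function(tp) {
      p <- panels[[tp]]
      cbind(data.frame(timepoint = as.numeric(sub("^t", "", tp))), p)
    }))
    write_table_csv(long, file.path(d, sprintf("biomarkers_%s.csv", pkg)))
  }
  # latent truth is quarantined: analysis stages never read truth/
  write_table_csv(trt$latent, file.path(d, "truth", "latent_responders.csv"))
  invisible(d)
}

read_patient_tables <- function(out_dir) {
  ctrl <- read_table_csv(require_artifact(out_dir, "simulate", "control_patients.csv"))
  trt <- read_table_csv(require_artifact(out_dir, "simulate", "treated_patients.csv"))
  list(control = ctrl, treated = trt, all = rbind(ctrl, trt))
}

adjusted_formula <- function(data, base_terms) {
  keep <- vapply(base_terms, function(v) length(unique(data[[v]])) > 1L, logical(1))
  stats::as.formula(paste("survival::Surv(survival_days, event) ~",
                          paste(base_terms[keep], collapse = " + ")))
}

surv_fit_rows <- function(model_name, fit) {
  data.frame(model = model_name, term = names(fit$coefficients),
             coef = unname(fit$coefficients), se = unname(fit$se),
             wald_chisq = unname(fit$wald_chisq), p = unname(fit$p),
             hazard_ratio = if (is.null(fit$hazard_ratios)) NA else
               unname(fit$hazard_ratios[names(fit$coefficients)]),
             event_time_ratio = if (is.null(fit$event_time_ratio)) NA else
               unname(fit$event_time_ratio[names(fit$coefficients)]),
             stringsAsFactors = FALSE)
}

stage_survive <- function(config, out_dir) {
  d <- stage_dir(out_dir, "survive")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(d, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  pats <- read_patient_tables(out_dir)
  all <- pats$all
  all$event <- as.logical(all$event)
  km_rows <- do.call(rbind, lapply(split(all, all$cohort), function(g) {
    km <- km_estimate(g$survival_days, g$event)
    data.frame(cohort = g$cohort[1], n = km$n, events = km$events,
               median_days = km$median, median_lcl = km$median_ci[1],
               median_ucl = km$median_ci[2])
  }))
  write_table_csv(km_rows, file.path(d, "km.csv"))
  lr <- logrank_test(all$survival_days, all$event, all$cohort, "logrank")
  wx <- logrank_test(all$survival_days, all$event, all$cohort, "wilcoxon")
  write_table_csv(data.frame(variant = c(lr$variant, wx$variant),
                             chisq = c(lr$statistic, wx$statistic),
                             df = c(lr$df, wx$df),
                             p = c(lr$p_value, wx$p_value)),
                  file.path(d, "logrank.csv"))
  base_terms <- c("cohort", "age", "sex", "baseline_alsfrs", "onset_site",
                  "latency_days", "riluzole")
  f <- adjusted_formula(all, base_terms)
  cox <- cox_fit(f, all)
  par_fit <- parametric_fit(f, all)
  f_int <- stats::update(f, . ~ . + cohort:age)
  par_int <- parametric_fit(f_int, all)
  aft <- aft_fit(f, all, dist = "weibull")
  fits <- rbind(surv_fit_rows("cox", cox),
                surv_fit_rows("parametric_exponential", par_fit),
                surv_fit_rows("parametric_age_interaction", par_int),
                surv_fit_rows("aft_weibull", aft))
  write_table_csv(fits, file.path(d, "fits.csv"))
  log_event(log_path, stage = "survive", models = 4,
            cox_loglik = cox$log_likelihood, aft_loglik = aft$log_likelihood)
  invisible(d)
}

stage_match <- function(config, out_dir) {
  d <- stage_dir(out_dir, "match")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  pats <- read_patient_tables(out_dir)
  ms <- match_controls(pats$treated, pats$control,
                       covariates = config$match$covariates,
                       k = config$match$k, seed = config$seeds$match)
  write_table_csv(as.data.frame(ms), file.path(d, "matched_sets.csv"))
  tost <- do.call(rbind, lapply(config$match$covariates, function(v) {
    x <- pats$treated[[v]]
    y <- pats$control[[v]][match(ms$control_id, pats$control$patient_id)]
    sd_pool <- sqrt((stats::var(x) + stats::var(y)) / 2)
    tr <- tost_equivalence(x, y, margin = config$thresholds$tost_margin_sd * sd_pool,
                           alpha = config$thresholds$alpha)
    data.frame(covariate = v, margin = tr$margin, estimate = tr$estimate,
               p_lower = tr$p_lower, p_upper = tr$p_upper, pass = tr$pass,
               degenerate = tr$degenerate)
  }))
  write_table_csv(tost, file.path(d, "tost.csv"))
  bs <- bootstrap_compare(ms, pats$treated, pats$control,
                          draws = config$match$draws,
                          subsample = config$match$subsample,
                          seed = config$seeds$match)
  thin <- bs$per_draw[seq_len(min(nrow(bs$per_draw), 1000L)), ]
  write_table_csv(thin, file.path(d, "bootstrap_draws.csv"))
  write_table_csv(data.frame(
    draws = bs$draws, subsample = bs$subsample,
    mean_of_medians_treated = bs$mean_of_medians["treated"],
    mean_of_medians_control = bs$mean_of_medians["control"],
    median_p = bs$median_p, p_min = bs$p_range[1], p_max = bs$p_range[2]),
    file.path(d, "bootstrap_summary.csv"))
  invisible(d)
}

stage_decline <- function(config, out_dir) {
  d <- stage_dir(out_dir, "decline")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  pats <- read_patient_tables(out_dir)
  visits <- rbind(
    read_table_csv(require_artifact(out_dir, "simulate", "control_visits.csv")),
    read_table_csv(require_artifact(out_dir, "simulate", "treated_visits.csv")))
  fit <- fit_decline(visits, pats$all, group_col = "cohort",
                     max_month = config$decline$max_month,
                     eval_month = config$decline$eval_month)
  coefs <- data.frame(term = rownames(fit$coefficients), fit$coefficients,
                      check.names = FALSE, row.names = NULL)
  write_table_csv(coefs, file.path(d, "decline_coefficients.csv"))
  write_table_csv(fit$prediction_grid, file.path(d, "prediction_grid.csv"))
  tw <- fit_decline_threeway(visits, pats$all, group_col = "cohort",
                             max_month = config$decline$max_month,
                             eval_month = config$decline$eval_month)
  write_table_csv(tw$latency_profile, file.path(d, "threeway_latency_profile.csv"))
  write_table_csv(data.frame(
    interaction_p = unname(fit$interaction_p[1]),
    group_difference = unname(fit$group_difference["estimate"]),
    group_difference_se = unname(fit$group_difference["se"]),
    eval_month = config$decline$eval_month,
    threeway_p = unname(tw$threeway_p[1]),
    singular_fallback = fit$singular_fallback),
    file.path(d, "decline_summary.csv"))
  invisible(d)
}

stage_respond <- function(config, out_dir) {
  d <- stage_dir(out_dir, "respond")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(d, "log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  pats <- read_patient_tables(out_dir)
  cv <- read_table_csv(require_artifact(out_dir, "simulate", "control_visits.csv"))
  tv <- read_table_csv(require_artifact(out_dir, "simulate", "treated_visits.csv"))
  sl_ctrl <- slope_table(cv, max_month = config$slope_window_months)
  sl_trt <- slope_table(tv, max_month = config$slope_window_months)
  model <- fit_survival_glm(pats$control, sl_ctrl)
  cf <- summary(model)$coefficients
  write_table_csv(data.frame(term = rownames(cf), cf, check.names = FALSE,
                             row.names = NULL),
                  file.path(d, "glm_coefficients.csv"))
  pred <- predict_survival(model, pats$treated, sl_trt)
  labels <- classify_response(pats$treated$survival_days,
                              !as.logical(pats$treated$event),
                              pred$predicted_days,
                              threshold = config$thresholds$responder_band,
                              patient_id = pats$treated$patient_id)
  log_event(log_path, stage = "respond",
            n_unpredictable = sum(pred$unpredictable),
            band_days = config$thresholds$responder_band)
  write_table_csv(as.data.frame(labels), file.path(d, "labels.csv"))
  write_table_csv(as.data.frame(waterfall(labels)), file.path(d, "waterfall.csv"))
  ctr <- response_survival_contrast(labels)
  write_table_csv(data.frame(
    group = names(ctr$medians), median_days = unname(ctr$medians),
    logrank_p = ctr$p_value, p_defined = ctr$p_defined),
    file.path(d, "contrast.csv"))
  # functional decline by responder group (database variable replaced)
  trt_lab <- merge(pats$treated, as.data.frame(labels)[, c("patient_id", "label")],
                   by = "patient_id")
  trt_lab <- trt_lab[trt_lab$label %in% c("responder", "non-responder"), ]
  dec_p <- NA_real_
  if (length(unique(trt_lab$label)) == 2L) {
    dec <- tryCatch(
      fit_decline(tv, trt_lab, group_col = "label",
                  max_month = config$decline$max_month,
                  eval_month = config$decline$eval_month),
      error = function(e) NULL)
    if (!is.null(dec)) dec_p <- unname(dec$interaction_p[1])
  }
  write_table_csv(data.frame(interaction_p = dec_p),
                  file.path(d, "responder_decline.csv"))
  invisible(d)
}

stage_signature <- function(config, out_dir) {
  d <- stage_dir(out_dir, "signature")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  labels <- read_table_csv(require_artifact(out_dir, "respond", "labels.csv"))
  panel_sets <- list(); types_list <- list()
  for (pkg in names(config$biomarkers)) {
    f <- file.path(out_dir, "simulate", sprintf("biomarkers_%s.csv", pkg))
    if (!file.exists(f)) next
    long <- read_table_csv(f)
    panels <- lapply(split(long, long$timepoint), function(p) {
      p$timepoint <- NULL
      p
    })
    names(panels) <- paste0("t", names(panels))
    panel_sets[[pkg]] <- panels
    vars <- setdiff(colnames(long), c("timepoint", "patient_id"))
    types_list[[pkg]] <- ifelse(vars %in% names(config$biomarkers[[pkg]]$ordinal_vars),
                                "ordinal", "scalar")
  }
  # baseline-anchored cytokine areas over the first 9 months
  if (!is.null(panel_sets$cytokines)) {
    pan <- panel_sets$cytokines
    vars <- setdiff(colnames(pan[[1]]), "patient_id")
    ids <- pan[["t0"]]$patient_id
    rows <- list()
    for (v in vars) {
      base <- pan[["t0"]][[v]][match(ids, pan[["t0"]]$patient_id)]
      vals <- sapply(c(3, 6, 9), function(m) {
        p <- pan[[paste0("t", m)]]
        if (is.null(p)) rep(NA_real_, length(ids)) else p[[v]][match(ids, p$patient_id)]
      })
      area <- vapply(seq_along(ids), function(i) {
        cytokine_auc(base[i], vals[i, ], months = c(3, 6, 9))
      }, numeric(1))
      rows[[v]] <- data.frame(patient_id = ids, variable = v, area = area,
                              stringsAsFactors = FALSE)
    }
    areas <- do.call(rbind, rows)
    rownames(areas) <- NULL
    write_table_csv(areas, file.path(d, "cytokine_auc.csv"))
    write_table_csv(auc_group_test(areas, labels),
                    file.path(d, "cytokine_auc_tests.csv"))
  }
  sig <- run_signature(panel_sets, labels, types_list = types_list,
                       windows = config$signature$windows,
                       n_components = 3L,
                       loading_cutoff = config$thresholds$loading_cutoff,
                       alpha = config$thresholds$alpha,
                       n_perm = config$signature$n_perm,
                       seed = config$seeds$signature)
  pc_tests <- do.call(rbind, lapply(sig, function(s) s$pc_tests))
  rownames(pc_tests) <- NULL
  write_table_csv(pc_tests, file.path(d, "pc_tests.csv"))
  for (wn in names(sig)) {
    s <- sig[[wn]]
    for (pkg in names(s$fits)) {
      L <- s$fits[[pkg]]$loadings
      write_table_csv(data.frame(variable = rownames(L), L, row.names = NULL),
                      file.path(d, sprintf("loadings_%s_%s.csv", pkg, wn)))
    }
    if (!s$meta$empty) {
      write_table_csv(data.frame(patient_id = names(s$meta$scores),
                                 meta_score = unname(s$meta$scores)),
                      file.path(d, sprintf("meta_scores_%s.csv", wn)))
    }
  }
  roc_rows <- do.call(rbind, lapply(sig, function(s) {
    data.frame(window = s$window,
               n_significant_pcs = if (is.null(s$pc_tests)) 0L else sum(s$pc_tests$significant),
               auc = if (is.null(s$roc)) NA_real_ else s$roc$auc,
               p = if (is.null(s$roc)) NA_real_ else s$roc$p_value)
  }))
  rownames(roc_rows) <- NULL
  write_table_csv(roc_rows, file.path(d, "roc.csv"))
  invisible(d)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing delimited
#' artifacts under `out_dir/<stage>/` and a JSON manifest with an md5 content
#' hash per artifact. Identical config and seeds reproduce identical hashes.
#' A stage whose upstream artifacts are missing raises an error naming the
#' stage to enable.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages stages to run this call (default: the config's enabled
#'   stages).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir, stages = config$stages) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config", call. = FALSE)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runners <- list(simulate = stage_simulate, survive = stage_survive,
                  match = stage_match, decline = stage_decline,
                  respond = stage_respond, signature = stage_signature)
  for (st in PIPELINE_STAGES) {
    if (st %in% stages) runners[[st]](config, out_dir)
  }
  rel <- sort(list.files(out_dir, recursive = TRUE))
  rel <- rel[basename(rel) != "manifest.json"]
  hashes <- unname(tools::md5sum(file.path(out_dir, rel)))
  manifest <- list(
    stages_run = intersect(PIPELINE_STAGES, stages),
    seed = config$seed,
    stage_seeds = config$seeds,
    artifacts = stats::setNames(as.list(hashes), rel)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

get_config_value <- function(config, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- config
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
    node <- node[[p]]
  }
  node
}

set_config_value <- function(config, key, value) {
  get_config_value(config, key)  # validates the path
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  expr <- paste0("config", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  config
}

#' Sensitivity sweep over pipeline parameters
#'
#' Runs the pipeline once per grid point (Cartesian product of the supplied
#' values) with a common seed and tabulates the headline outputs: responder
#' label counts, the late-window meta-PC ROC AUC and the decline interaction
#' p-value (when the decline stage is enabled).
#'
#' @param config a [run_config()].
#' @param grid named list: config keys in dot notation (e.g.
#'   `thresholds.responder_band`) mapped to value vectors. An empty grid
#'   yields an empty table.
#' @param out_root directory receiving one subdirectory per grid point.
#' @param stages stages to run per grid point.
#' @return data frame: one row per grid point with the swept values and the
#'   headline outputs.
#' @export
sensitivity_sweep <- function(config, grid, out_root = tempfile("sweep"),
                              stages = c("simulate", "respond", "signature")) {
  if (!length(grid)) {
    return(data.frame(grid_point = integer(0)))
  }
  for (key in names(grid)) get_config_value(config, key)  # unknown key -> error
  points <- expand.grid(grid, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    cfg <- config
    for (key in names(grid)) cfg <- set_config_value(cfg, key, points[i, key])
    od <- file.path(out_root, sprintf("point_%03d", i))
    run_pipeline(cfg, od, stages = stages)
    labels <- read_table_csv(file.path(od, "respond", "labels.csv"))
    counts <- table(factor(labels$label,
                           levels = c("responder", "non-responder", "non-assignable")))
    roc <- tryCatch(read_table_csv(file.path(od, "signature", "roc.csv")),
                    error = function(e) NULL)
    auc <- if (is.null(roc) || !nrow(roc)) NA_real_ else roc$auc[which.max(roc$window)]
    dec <- tryCatch(read_table_csv(file.path(od, "decline", "decline_summary.csv")),
                    error = function(e) NULL)
    rows[[i]] <- cbind(data.frame(grid_point = i), points[i, , drop = FALSE],
                       data.frame(n_responder = as.integer(counts["responder"]),
                                  n_nonresponder = as.integer(counts["non-responder"]),
                                  n_nonassignable = as.integer(counts["non-assignable"]),
                                  meta_auc = auc,
                                  decline_interaction_p = if (is.null(dec)) NA_real_ else dec$interaction_p))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
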