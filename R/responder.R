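# Residual-based treatment-response classification: predicted vs observed
# survival, three-level labels, waterfall ordering and the survival contrast
# between label groups.

#' Predict individual survival for a patient table
#'
#' Joins per-patient slopes, applies an [expsurv()] model and returns one row
#' per patient. Censored patients are predicted like everybody else; patients
#' with a nonpositive linear predictor or missing covariates are flagged
#' `unpredictable`.
#'
#' @param model an `expsurv` fit (see [fit_survival_glm()]).
#' @param patients patient table.
#' @param slopes slope table ([slope_table()]); omit if the model formula does
#'   not use `slope`.
#' @return data frame: `patient_id`, `predicted_days`, `unpredictable`.
#' @export
predict_survival <- function(model, patients, slopes = NULL) {
  d <- if (is.null(slopes)) patients else merge(patients, slopes, by = "patient_id",
                                                all.x = TRUE, sort = FALSE)
  d <- d[match(patients$patient_id, d$patient_id), , drop = FALSE]
  pred <- predict(model, d)
  data.frame(patient_id = patients$patient_id,
             predicted_days = as.numeric(pred),
             unpredictable = is.na(as.numeric(pred)),
             stringsAsFactors = FALSE)
}

#' Classify treatment response from survival residuals
#'
#' The residual is observed minus model-predicted survival (days). A patient
#' is a `responder` when the residual exceeds `+threshold` (censored patients
#' qualify too: they have already outlived their prediction), a
#' `non-responder` when the residual is below `-threshold` and death was
#' observed, and `non-assignable` otherwise - in particular a censored
#' patient short of `+threshold`, whose shortfall censoring makes unprovable.
#' Patients without a prediction keep an `NA` label.
#'
#' @param observed observed survival/follow-up time, days.
#' @param censored logical, `TRUE` when follow-up ended without death.
#' @param predicted model-predicted survival, days (`NA` = unpredictable).
#' @param threshold non-negative "negligible difference" band, days.
#' @param patient_id optional identifiers.
#' @return data frame of class `responder_labels`: `patient_id`, `observed`,
#'   `predicted`, `censored`, `residual`, `label` (factor responder /
#'   non-responder / non-assignable).
#' @export
classify_response <- function(observed, censored, predicted, threshold = 60,
                              patient_id = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("invalid `threshold`: must be a non-negative number of days", call. = FALSE)
  }
  censored <- as.logical(censored)
  if (is.null(patient_id)) patient_id <- sprintf("P%04d", seq_along(observed))
  residual <- observed - predicted
  lv <- c("responder", "non-responder", "non-assignable")
  label <- rep(NA_character_, length(observed))
  ok <- !is.na(residual)
  label[ok & residual > threshold] <- "responder"
  label[ok & residual < -threshold & !censored] <- "non-responder"
  label[ok & is.na(label)] <- "non-assignable"
  out <- data.frame(patient_id = patient_id, observed = observed,
                    predicted = predicted, censored = censored,
                    residual = residual,
                    label = factor(label, levels = lv),
                    stringsAsFactors = FALSE)
  class(out) <- c("responder_labels", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Waterfall ordering of survival residuals
#'
#' Residuals sorted in descending order (ties broken by patient id), ready
#' for a waterfall plot of observed-minus-predicted survival.
#'
#' @param labels a `responder_labels` table from [classify_response()].
#' @return the same table, ordered, with a `rank` column.
#' @export
waterfall <- function(labels) {
  if (nrow(labels) < 1L) stop("need at least one labeled patient", call. = FALSE)
  ord <- order(-labels$residual, labels$patient_id, na.last = TRUE)
  out <- labels[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Plot a waterfall of observed-minus-predicted survival
#'
#' @param x a `responder_labels` table.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.responder_labels <- function(x, ...) {
  w <- waterfall(x)
  cols <- c(responder = "darkcyan", `non-responder` = "salmon",
            `non-assignable` = "grey80")
  graphics::barplot(w$residual, col = cols[as.character(w$label)],
                    border = NA, ylab = "Observed - predicted survival (days)",
                    ...)
  invisible(x)
}

#' Survival contrast between responder label groups
#'
#' Kaplan-Meier curves per label group plus a log-rank comparison, delegated
#' to the survival engine. Groups of size one (or a single usable group)
#' yield an `NA` p-value with `p_defined = FALSE` rather than an error.
#'
#' @param labels `responder_labels` table.
#' @param groups which labels to contrast (default responder vs
#'   non-responder).
#' @return list: `curves` (named list of [km_estimate()] results), `medians`,
#'   `test` ([logrank_test()] result or `NULL`), `p_value`, `p_defined`.
#' @export
response_survival_contrast <- function(labels,
                                       groups = c("responder", "non-responder")) {
  d <- labels[!is.na(labels$label) & labels$label %in% groups, , drop = FALSE]
  d$event <- !d$censored
  curves <- lapply(split(d, droplevels(d$label)), function(g) {
    km_estimate(g$observed, g$event)
  })
  medians <- vapply(curves, function(k) k$median, numeric(1))
  sizes <- table(droplevels(d$label))
  testable <- length(sizes) >= 2L && all(sizes >= 2L) && sum(d$event) >= 1L
  test <- if (testable) {
    logrank_test(d$observed, d$event, droplevels(d$label))
  } else {
    NULL
  }
  list(curves = curves, medians = medians, test = test,
       p_value = if (testable) test$p_value else NA_real_,
       p_defined = testable)
}
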