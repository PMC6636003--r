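# Leave-one-out influence analysis for a biomarker panel.

#' Leave-one-out outlier influence analysis
#'
#' Re-fits and re-evaluates the whole panel pipeline (logistic fit, ROC,
#' cutoff at the sensitivity floor, stratification, log-rank) once per
#' held-out patient, quantifying how much each single patient moves the
#' panel's in-sample AUC.  A single outlying, misclassified patient —
#' e.g. one with exceptionally high marker levels for their response
#' group — shows up as the largest AUC shift.
#'
#' @param markers Data frame of marker columns, one row per patient
#'   (`patient_id` column optional).
#' @param labels Response label per patient.
#' @param times,events Survival times and event flags per patient.
#' @param positive_class Label the panel score models.
#' @param sens_floor Sensitivity floor for [derive_cutoff()].
#' @param delta Absolute AUC shift beyond which a patient is flagged
#'   influential.
#' @return A tibble, one row per held-out patient: `patient_id`, `auc`,
#'   `spec_at_sens90`, `logrank_p` with that patient excluded,
#'   `auc_shift` relative to the full-cohort AUC, `flagged`, and
#'   `valid` (FALSE when exclusion collapses a class or a stratum; such
#'   rows carry NA metrics but are never dropped).
#' @export
loo_outlier_analysis <- function(markers, labels, times, events,
                                 positive_class = "Limited",
                                 sens_floor = 0.90, delta = 0.05) {
  df <- as.data.frame(markers)
  n <- nrow(df)
  labels <- as.character(labels)
  if (length(labels) != n || length(times) != n || length(events) != n) {
    ms1_abort("markers, labels, times and events must align")
  }
  if (min(table(labels)) < 3L) {
    ms1_abort("leave-one-out analysis needs >= 3 patients per class")
  }
  patient_ids <- df$patient_id %||% sprintf("patient_%02d", seq_len(n))

  evaluate <- function(idx) {
    model <- fit_logistic_panel(df[idx, , drop = FALSE], labels[idx],
                                positive_class = positive_class)
    scores <- predict(model, df[idx, , drop = FALSE])
    roc <- roc_curve(scores, labels[idx], positive_class)
    cutoff <- derive_cutoff(roc, sens_at_least = sens_floor)
    strata <- ifelse(scores >= cutoff, "Biomarker-positive",
                     "Biomarker-negative")
    lr_p <- if (length(unique(strata)) == 2L) {
      pos <- strata == "Biomarker-positive"
      tryCatch(
        logrank_test(times[idx][pos], events[idx][pos],
                     times[idx][!pos], events[idx][!pos])$p,
        ms1panel_error = function(e) NA_real_
      )
    } else {
      NA_real_
    }
    list(auc = roc$auc, spec_at_sens90 = roc$spec_at_sens90, logrank_p = lr_p)
  }

  full <- evaluate(seq_len(n))
  rows <- purrr::map(seq_len(n), function(i) {
    idx <- setdiff(seq_len(n), i)
    if (length(unique(labels[idx])) < 2L || min(table(labels[idx])) < 2L) {
      return(tibble::tibble(
        patient_id = patient_ids[i], auc = NA_real_,
        spec_at_sens90 = NA_real_, logrank_p = NA_real_,
        auc_shift = NA_real_, flagged = NA, valid = FALSE
      ))
    }
    res <- evaluate(idx)
    shift <- res$auc - full$auc
    tibble::tibble(
      patient_id = patient_ids[i], auc = res$auc,
      spec_at_sens90 = res$spec_at_sens90, logrank_p = res$logrank_p,
      auc_shift = shift, flagged = abs(shift) > delta, valid = TRUE
    )
  })
  dplyr::bind_rows(rows)
}
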