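# ROC curves, operating points and cutoff-based patient stratification.

#' ROC curve with the panel's operating points
#'
#' Builds the step ROC curve over all distinct score thresholds with the
#' `>=`-threshold convention (a patient is called positive when its
#' score is at least the threshold; no interpolation).  The AUC uses the
#' pair-counting (concordance) formulation with ties counted 1/2.  Two
#' operating points are reported: the maximum sensitivity among curve
#' points with specificity >= 0.90, and the maximum specificity among
#' points with sensitivity >= 0.90.
#'
#' @param scores Numeric score per patient (higher = more
#'   positive-like).
#' @param labels Class label per patient.
#' @param positive_class Label treated as positive.
#' @return An object of class `roc_result`: `curve` (tibble `threshold`,
#'   `sensitivity`, `specificity`, thresholds ascending), `auc`,
#'   `sens_at_spec90`, `spec_at_sens90`, `positive_class`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_curve(c(0.9, 0.4, 0.6, 0.1), c("L", "L", "G", "G"), "L")
#' @export
roc_curve <- function(scores, labels, positive_class) {
  if (length(scores) != length(labels)) {
    ms1_abort("`scores` and `labels` differ in length")
  }
  if (anyNA(scores) || any(!is.finite(scores))) {
    ms1_abort("scores must be finite")
  }
  labels <- as.character(labels)
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  if (length(pos) == 0L || length(neg) == 0L) {
    ms1_abort("both classes must be present")
  }

  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))

  # Pair-counting AUC, ties at 1/2.
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  auc <- mean(cmp)

  curve <- tibble::tibble(threshold = thresholds, sensitivity = sens,
                          specificity = spec)
  structure(
    list(
      curve = curve, auc = auc,
      sens_at_spec90 = max(sens[spec >= 0.90]),
      spec_at_sens90 = max(spec[sens >= 0.90]),
      positive_class = positive_class,
      n_pos = length(pos), n_neg = length(neg)
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (%d pos / %d neg, positive = '%s'); sens@spec90 %.2f, spec@sens90 %.2f\n",
    x$auc, x$n_pos, x$n_neg, x$positive_class,
    x$sens_at_spec90, x$spec_at_sens90
  ))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    sens_at_spec90 = x$sens_at_spec90,
    spec_at_sens90 = x$spec_at_sens90,
    n_pos = x$n_pos, n_neg = x$n_neg,
    positive_class = x$positive_class
  )
}

#' Derive the panel cutoff from a ROC curve
#'
#' Returns the score threshold that maximizes specificity subject to a
#' sensitivity floor (default 0.90: a predictive biomarker should miss
#' few patients who would benefit from treatment).  Among equally
#' specific qualifying points the higher threshold is returned.
#'
#' @param roc A `roc_result`.
#' @param sens_at_least Sensitivity floor in \[0, 1\].
#' @return The cutoff threshold (numeric scalar).
#' @export
derive_cutoff <- function(roc, sens_at_least = 0.90) {
  stopifnot(inherits(roc, "roc_result"))
  check_number(sens_at_least, "sens_at_least", lower = 0)
  curve <- roc$curve
  ok <- curve$sensitivity >= sens_at_least
  if (!any(ok)) {
    ms1_abort(sprintf(
      "sensitivity floor %g unattainable; maximum attainable sensitivity is %g",
      sens_at_least, max(curve$sensitivity)
    ))
  }
  cand <- curve[ok, ]
  cand <- cand[cand$specificity == max(cand$specificity), ]
  max(cand$threshold)
}

#' Stratify patients by the panel cutoff
#'
#' Scores every patient with the fitted panel and labels those at or
#' above the cutoff `Biomarker-positive` (predicted member of the
#' model's positive class — with the default orientation, a predicted
#' Limited-responder) and the rest `Biomarker-negative`.  A score
#' exactly at the cutoff is Biomarker-positive.
#'
#' @param model A `panel_model`.
#' @param cutoff Score threshold from [derive_cutoff()].
#' @param markers Data frame covering the model's markers; a
#'   `patient_id` column is carried through.
#' @return A tibble: `patient_id` (when available), `score`,
#'   `biomarker_status` (`"Biomarker-positive"`/`"Biomarker-negative"`).
#' @export
stratify_patients <- function(model, cutoff, markers) {
  stopifnot(inherits(model, "panel_model"))
  check_number(cutoff, "cutoff", lower = -Inf)
  score <- predict(model, markers)
  out <- tibble::tibble(
    score = score,
    biomarker_status = ifelse(score >= cutoff,
                              "Biomarker-positive", "Biomarker-negative")
  )
  df <- as.data.frame(markers)
  if (!is.null(df$patient_id)) {
    out <- dplyr::bind_cols(tibble::tibble(patient_id = df$patient_id), out)
  }
  out
}

#' Both sensitivity orientations of a panel evaluation
#'
#' The panel score models the probability of limited response, so its
#' ROC sensitivity refers to detecting Limited-responders.  Clinically
#' the complementary orientation — how reliably Good-responders are
#' recognized so they receive treatment — matters too.  This helper
#' reports operating points under both orientations of the same scores.
#'
#' @param scores Panel scores (probability of the limited class).
#' @param labels Response labels.
#' @param limited_class,good_class Label values.
#' @return A two-row tibble: one row per orientation with `auc`,
#'   `sens_at_spec90`, `spec_at_sens90`.
#' @export
roc_both_orientations <- function(scores, labels,
                                  limited_class = "Limited",
                                  good_class = "Good") {
  roc_l <- roc_curve(scores, labels, limited_class)
  roc_g <- roc_curve(-scores, labels, good_class)
  dplyr::bind_rows(
    dplyr::mutate(glance(roc_l), orientation = "detect-Limited"),
    dplyr::mutate(glance(roc_g), orientation = "detect-Good")
  )
}
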