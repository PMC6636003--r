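# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   geom_abline geom_tile geom_vline geom_hline labs theme_bw
#'   scale_fill_gradient2 element_text theme coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, dplyr::desc(.data$threshold))
  ggplot(curve, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_step(direction = "hv", linewidth = 0.8, colour = "#2166ac") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    coord_equal() +
    labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (positive = %s), AUC = %.3f",
                      object$positive_class, object$auc)
    ) +
    theme_bw()
}

#' Plot Kaplan-Meier curves of a survival comparison
#'
#' @param object A `survival_comparison` or single `km_fit`.
#' @param ... Unused.
#' @return A ggplot of the stepped survival functions.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  dat <- tidy(object)
  start <- dplyr::distinct(dat, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  dat <- dplyr::bind_rows(start, dat)
  ggplot(dat, aes(x = .data$time, y = .data$survival,
                  colour = .data$group)) +
    geom_step(direction = "hv", linewidth = 0.8) +
    geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey60") +
    labs(
      x = "Months", y = "Survival probability", colour = NULL,
      title = sprintf("Log-rank p = %.3g", object$logrank_p)
    ) +
    theme_bw()
}

#' @rdname autoplot.survival_comparison
#' @export
autoplot.km_fit <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tidy(object)[c("time", "survival")]
  )
  ggplot(dat, aes(x = .data$time, y = .data$survival)) +
    geom_step(direction = "hv", linewidth = 0.8, colour = "#2166ac") +
    labs(x = "Months", y = "Survival probability") +
    theme_bw()
}

#' Plot PCA sample scores
#'
#' @param object A `pca_result` (needs >= 2 components).
#' @param colour_by Optional vector (e.g. response group), one value per
#'   sample, used to colour the points.
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @export
autoplot.pca_result <- function(object, colour_by = NULL, ...) {
  if (ncol(object$scores) < 2L) {
    ms1_abort("PCA score plot needs at least 2 components")
  }
  ev <- object$explained_variance_fraction
  dat <- tibble::tibble(
    pc1 = object$scores[, 1], pc2 = object$scores[, 2]
  )
  p <- if (is.null(colour_by)) {
    ggplot(dat, aes(x = .data$pc1, y = .data$pc2)) + geom_point(size = 2)
  } else {
    dat$group <- colour_by
    ggplot(dat, aes(x = .data$pc1, y = .data$pc2, colour = .data$group)) +
      geom_point(size = 2)
  }
  p +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = NULL
    ) +
    theme_bw()
}

#' Heatmap of clustered features
#'
#' @param object A `feature_clustering`.
#' @param ... Unused.
#' @return A ggplot tile heatmap with rows in dendrogram leaf order and
#'   colour encoding log2 intensity.
#' @export
autoplot.feature_clustering <- function(object, ...) {
  dat <- object$heatmap
  mid <- median(dat$log2_ipm)
  ggplot(dat, aes(x = .data$sample_id, y = .data$feature_id,
                  fill = .data$log2_ipm)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = mid, low = "#2166ac", mid = "white",
                         high = "#b2182b", name = "log2 IPM") +
    labs(x = NULL, y = NULL) +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Volcano-style view of a differential result table
#'
#' @param results Differential tibble from [bd_differential()],
#'   [tid_differential()] or [variant_differential()].
#' @param alpha Significance line.
#' @return A ggplot of log2(Good/Limited ratio) against -log10 p.
#' @export
plot_differential <- function(results, alpha = 0.05) {
  check_data_frame(results, "results",
                   c("ratio_good_over_limited", "p_value", "significant"))
  dat <- dplyr::filter(results, is.finite(.data$ratio_good_over_limited),
                       .data$ratio_good_over_limited > 0)
  ggplot(dat, aes(x = log2(.data$ratio_good_over_limited),
                  y = -log10(pmax(.data$p_value, 1e-300)),
                  colour = .data$significant)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed",
               colour = "grey50") +
    geom_vline(xintercept = 0, linetype = "dotted", colour = "grey70") +
    labs(x = "log2 (Good / Limited)", y = "-log10 p", colour = "p < alpha") +
    theme_bw()
}
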