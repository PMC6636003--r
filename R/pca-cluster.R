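# Sample-level PCA and feature-level hierarchical clustering views of a
# quantification matrix.

#' Principal component analysis of samples
#'
#' Centers each feature and projects samples onto the eigenvectors of
#' the sample covariance matrix (via [stats::prcomp()]).  Explained
#' variance fractions are reported over all components and sum to 1.
#'
#' @param x A `quant_matrix` (features x samples; samples become
#'   observations) or a plain samples-x-features numeric matrix.
#' @param n_components Number of components to keep in scores and
#'   loadings.
#' @param log_transform Apply log2(x + epsilon) before the PCA (used for
#'   IPM intensities).
#' @param epsilon Offset for the log transform.
#' @return A list of class `pca_result`: `scores` (samples x
#'   components), `loadings` (features x components),
#'   `explained_variance_fraction` (all components, sums to 1), and
#'   `center`.
#' @export
pca_transform <- function(x, n_components = 2, log_transform = FALSE,
                          epsilon = 1) {
  if (inherits(x, "quant_matrix")) x <- t(x$values)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) ms1_abort("PCA needs at least 2 samples")
  if (log_transform) x <- log2(x + epsilon)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    ms1_abort(sprintf("`n_components` = %d exceeds the maximum rank %d",
                      n_components, max_rank))
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  structure(
    list(
      scores = fit$x[, seq_len(n_components), drop = FALSE],
      loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
      explained_variance_fraction = ev / sum(ev),
      center = fit$center
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance_fraction
  k <- ncol(x$scores)
  cat(sprintf("<pca_result> %d samples, %d component(s); PC1 %.1f%%%s\n",
              nrow(x$scores), k, 100 * ev[1],
              if (k > 1) sprintf(", PC2 %.1f%%", 100 * ev[2]) else ""))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  scores <- tibble::as_tibble(x$scores)
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$scores)), scores)
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = ncol(x$scores),
    pc1_variance_fraction = x$explained_variance_fraction[1],
    pc2_variance_fraction = if (length(x$explained_variance_fraction) > 1) {
      x$explained_variance_fraction[2]
    } else NA_real_
  )
}

#' Hierarchical clustering of features with a heatmap table
#'
#' Agglomerative clustering of features on log2-transformed intensities.
#' Features are canonically sorted by id before distances are computed,
#' so the merge tree and leaf order are invariant to the input row
#' order; with that fixed input order [stats::hclust()] is fully
#' deterministic.
#'
#' @param x A `quant_matrix` or features x samples numeric matrix.
#' @param linkage `"average"` or `"complete"`.
#' @param distance `"euclidean"` or `"correlation"`
#'   (1 - Pearson on feature profiles).
#' @param epsilon Offset inside the log2 transform.
#' @return A list of class `feature_clustering`: `hclust` (the merge
#'   tree), `leaf_order` (feature ids in dendrogram order) and
#'   `heatmap` (long tibble `feature_id`, `sample_id`, `log2_ipm`,
#'   rows in leaf order).
#' @export
cluster_features <- function(x, linkage = c("average", "complete"),
                             distance = c("euclidean", "correlation"),
                             epsilon = 1) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  m <- if (inherits(x, "quant_matrix")) x$values else as.matrix(x)
  if (nrow(m) < 2L) ms1_abort("clustering needs at least 2 features")
  m <- m[order(rownames(m)), , drop = FALSE]
  lg <- log2(m + epsilon)
  d <- switch(distance,
    euclidean = dist(lg),
    correlation = {
      profile_sd <- apply(lg, 1L, sd)
      if (any(profile_sd == 0)) {
        ms1_abort("correlation distance undefined for constant feature profiles")
      }
      stats::as.dist(1 - cor(t(lg)))
    }
  )
  tree <- hclust(d, method = linkage)
  leaf_order <- tree$labels[tree$order]
  heat <- tibble::tibble(
    feature_id = factor(rep(rownames(lg), times = ncol(lg)),
                        levels = leaf_order),
    sample_id = rep(colnames(lg) %||% as.character(seq_len(ncol(lg))),
                    each = nrow(lg)),
    log2_ipm = as.vector(lg)
  )
  structure(
    list(hclust = tree, leaf_order = leaf_order,
         heatmap = dplyr::arrange(heat, .data$feature_id),
         linkage = linkage, distance = distance),
    class = "feature_clustering"
  )
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering> %d features, %s linkage, %s distance\n",
              length(x$leaf_order), x$linkage, x$distance))
  invisible(x)
}

#' Export a feature dendrogram as Newick text
#'
#' @param clustering A `feature_clustering`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "feature_clustering"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    ms1_abort("Newick export needs the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
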