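# BD/TID discovery, glyco classification, variant counts, PCA, clustering.

test_that("pooled t statistic matches the hand-evaluated formula", {
  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0214, tolerance = 1e-2)
  # symmetry and antisymmetry
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  swapped <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
})

test_that("degenerate variance follows the documented contract", {
  expect_equal(two_sample_t(c(5, 5, 5), c(5, 5))$p, 1)
  expect_error(two_sample_t(c(5, 5), c(7, 7)), "infinite")
  expect_error(two_sample_t(1, c(2, 3)), "at least 2")
})

make_protein_qm <- function(values) {
  ms1panel:::new_quant_matrix(values, NULL, "protein")
}

make_samples <- function(n_good, n_limited) {
  pats <- c(sprintf("G%02d", seq_len(n_good)),
            sprintf("L%02d", seq_len(n_limited)))
  grp <- c(rep("Good", n_good), rep("Limited", n_limited))
  tibble::tibble(
    run_id = c(paste0(pats, "_baseline"), paste0(pats, "_post")),
    patient_id = rep(pats, 2),
    timepoint = rep(c("baseline", "post"), each = length(pats)),
    response_group = rep(grp, 2)
  )
}

test_that("BD discovery flags a planted baseline effect and not a flat protein", {
  set.seed(201)
  samples <- make_samples(8, 8)
  base_cols <- samples$run_id[samples$timepoint == "baseline"]
  values <- matrix(rlnorm(2 * 32, log(100), 0.2), 2, 32,
                   dimnames = list(c("shifted", "flat"), samples$run_id))
  good_base <- samples$run_id[samples$timepoint == "baseline" &
                                samples$response_group == "Good"]
  values["shifted", good_base] <- values["shifted", good_base] * 4
  res <- bd_differential(make_protein_qm(values), samples)
  expect_true(res$significant[res$feature_id == "shifted"])
  expect_false(res$significant[res$feature_id == "flat"])
  expect_identical(unique(res$statistic_basis), "baseline_abundance")
  # constant protein with equal means is reported p = 1, not an error
  values["flat", ] <- 100
  res2 <- bd_differential(make_protein_qm(values), samples)
  expect_equal(res2$p_value[res2$feature_id == "flat"], 1)
})

test_that("BD needs at least two patients per group", {
  samples <- make_samples(1, 8)
  values <- matrix(rlnorm(18), 1, 18,
                   dimnames = list("p", samples$run_id))
  expect_error(bd_differential(make_protein_qm(values), samples),
               "at least 2")
})

test_that("TID uses post/baseline ratios with an epsilon floor", {
  set.seed(202)
  samples <- make_samples(6, 6)
  values <- matrix(rlnorm(2 * 24, log(100), 0.1), 2, 24,
                   dimnames = list(c("induced", "stable"), samples$run_id))
  good_post <- samples$run_id[samples$timepoint == "post" &
                                samples$response_group == "Good"]
  values["induced", good_post] <- values["induced", good_post] * 8
  res <- tid_differential(make_protein_qm(values), samples)
  expect_true(res$significant[res$feature_id == "induced"])
  expect_false(res$significant[res$feature_id == "stable"])

  # identical baseline and post matrices: all ratios ~1, nothing flagged
  flat <- values
  for (p in unique(samples$patient_id)) {
    flat[, paste0(p, "_post")] <- flat[, paste0(p, "_baseline")]
  }
  res_flat <- tid_differential(make_protein_qm(flat), samples)
  expect_false(any(res_flat$significant))

  # zero baseline cells stay finite through the epsilon floor
  zero <- values
  zero["stable", paste0("G01", "_baseline")] <- 0
  res_zero <- tid_differential(make_protein_qm(zero), samples)
  expect_true(all(is.finite(res_zero$t_statistic)))
})

test_that("unpaired patients abort with their ids", {
  samples <- make_samples(3, 3)[-1, ]   # drop one baseline run
  values <- matrix(rlnorm(11), 1, 11,
                   dimnames = list("p", samples$run_id))
  expect_error(tid_differential(make_protein_qm(values), samples), "G01")
})

test_that("glycopeptide classification follows the N-X-S/T sequon rule", {
  expect_true(classify_glycopeptide("AN[+0.98402]GSK", "MMANGSKLL"))
  expect_false(classify_glycopeptide("AN[+0.98402]PSK", "MMANPSKLL"))
  # deamidated N too close to the protein C-terminus: no full sequon
  expect_false(classify_glycopeptide("AN[+0.98402]", "MMAN"))
  # sequon completed by the protein context beyond the peptide boundary
  expect_true(classify_glycopeptide("AN[+0.98402]", "MMANGS"))
  # non-deamidated peptides are never glyco
  expect_false(classify_glycopeptide("ANGSK", "MMANGSKLL"))
  expect_error(classify_glycopeptide("WWWK", "MMANGSKLL"), "not found")
})

test_that("glyco classifier agrees with a regex oracle on random proteins", {
  set.seed(203)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_checked <- 0
  for (i in 1:2000) {
    prot <- paste(sample(aas, 40, replace = TRUE), collapse = "")
    start <- sample(1:20, 1)
    pep <- substr(prot, start, start + 14)
    npos <- which(strsplit(pep, "")[[1]] == "N")
    if (length(npos) == 0L) next
    pick <- npos[sample(length(npos), 1)]
    modified <- paste0(substr(pep, 1, pick - 1), "N[+0.98402]",
                       substr(pep, pick + 1, nchar(pep)))
    # regex oracle in full protein context at the absolute position
    abs_pos <- start + pick - 1
    oracle <- grepl("^N[^P][ST]", substr(prot, abs_pos, abs_pos + 2))
    if (gregexpr(pep, prot, fixed = TRUE)[[1]][1] != start) next  # ambiguous
    expect_identical(classify_glycopeptide(modified, prot), oracle)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 500)
})

test_that("variant spectral counts separate planted carrier groups", {
  counts <- rbind(var1 = c(5L, 6L, 7L, 0L, 0L, 1L),
                  zero = c(0L, 0L, 0L, 0L, 0L, 0L))
  colnames(counts) <- sprintf("P%d", 1:6)
  groups <- rep(c("Good", "Limited"), each = 3)
  res <- variant_differential(counts, groups)
  v1 <- res[res$feature_id == "var1", ]
  expect_true(v1$significant)
  # independent pooled-t oracle: t = 8.5, df = 4
  expect_equal(v1$t_statistic, 8.5, tolerance = 1e-9)
  z <- res[res$feature_id == "zero", ]
  expect_equal(z$p_value, 1)
  expect_false(z$significant)
  # identical count vectors across groups: p = 1
  same <- rbind(v = c(2L, 3L, 4L, 2L, 3L, 4L))
  colnames(same) <- colnames(counts)
  expect_equal(variant_differential(same, groups)$p_value, 1)
  # ordering by p value
  expect_equal(res$feature_id, c("var1", "zero"))
})

test_that("cohort variant counts are restricted to carriers and recoverable", {
  cohort <- tiny_cohort()
  counts <- variant_spectral_counts(cohort)
  carriers <- cohort$truth$variant_carriers
  expect_true(all(rownames(counts) %in% unique(carriers$peptide_id)))
  for (vid in rownames(counts)) {
    non_carriers <- setdiff(colnames(counts),
                            carriers$patient_id[carriers$peptide_id == vid])
    expect_true(all(counts[vid, non_carriers] == 0))
  }
})

test_that("PCA explains rank-1 data with one component and reconstructs", {
  line <- cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  res <- pca_transform(line, n_components = 1)
  expect_equal(res$explained_variance_fraction[1], 1, tolerance = 1e-12)

  set.seed(204)
  m <- matrix(rnorm(60), 10, 6)
  rownames(m) <- sprintf("s%d", 1:10)
  full <- pca_transform(m, n_components = 6)
  expect_equal(sum(full$explained_variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(full$explained_variance_fraction) <= 1e-12))
  # score covariance is diagonal
  cv <- cov(full$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # full-rank reconstruction
  recon <- full$scores %*% t(full$loadings) +
    matrix(full$center, 10, 6, byrow = TRUE)
  expect_lt(norm(recon - m, "F") / norm(m, "F"), 1e-8)
  expect_error(pca_transform(m, n_components = 7), "rank")
})

test_that("hierarchical clustering separates well-separated blocks", {
  set.seed(205)
  block1 <- matrix(rnorm(40, 0, 0.1), 4, 10)
  block2 <- matrix(rnorm(40, 50, 0.1), 4, 10)
  m <- rbind(block1, block2)
  rownames(m) <- c(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  colnames(m) <- sprintf("s%d", 1:10)
  cl <- cluster_features(2^m - 1, linkage = "average")   # log2(x+1) undone
  top2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(top2[sprintf("a%d", 1:4)])), 1)
  expect_equal(length(unique(top2[sprintf("b%d", 1:4)])), 1)
  expect_false(top2[["a1"]] == top2[["b1"]])

  # two leaves merge at their pairwise distance
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("u", "v"), c("s1", "s2")))
  cl2 <- cluster_features(2^two - 1)
  expect_equal(cl2$hclust$height, 5)   # 3-4-5 triangle

  # permuting input feature order changes nothing
  perm <- m[sample(nrow(m)), ]
  cl3 <- cluster_features(2^perm - 1, linkage = "average")
  expect_identical(cl$leaf_order, cl3$leaf_order)
  expect_equal(cl$hclust$height, cl3$hclust$height)
  expect_error(cluster_features(m[1, , drop = FALSE]), "at least 2")
})
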