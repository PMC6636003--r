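# BD/TID protein discovery, glycopeptide classification and variant
# spectral-count comparison.

#' Pooled-variance two-sample Student's t test
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = TRUE` that adds
#' the degenerate-variance contract used throughout the differential
#' module: when both groups are constant with equal means the result is
#' t = 0, p = 1; when they are constant with unequal means the statistic
#' is infinite and the call fails.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df` and `p` (two-sided).
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    ms1_abort("each group needs at least 2 values")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1))
    }
    ms1_abort("zero variance with unequal means: t statistic is infinite")
  }
  fit <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

# Run the pooled t across matrix rows and assemble a differential table.
differential_table <- function(values, is_good, basis, alpha, adjust,
                               degenerate = c("fail", "infinite")) {
  degenerate <- match.arg(degenerate)
  if (sum(is_good) < 2L || sum(!is_good) < 2L) {
    ms1_abort("each response group needs at least 2 samples")
  }
  res <- purrr::map(seq_len(nrow(values)), function(i) {
    a <- values[i, is_good]
    b <- values[i, !is_good]
    if (degenerate == "infinite" && var(a) == 0 && var(b) == 0 &&
        mean(a) != mean(b)) {
      # Exact integer ties make constant-unequal rows routine for
      # spectral counts; report them as maximally significant instead of
      # failing the whole comparison.
      return(list(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2L, p = 0))
    }
    two_sample_t(a, b)
  })
  out <- tibble::tibble(
    feature_id = rownames(values),
    mean_good = rowMeans(values[, is_good, drop = FALSE]),
    mean_limited = rowMeans(values[, !is_good, drop = FALSE]),
    statistic_basis = basis,
    t_statistic = purrr::map_dbl(res, "t"),
    df = purrr::map_dbl(res, "df"),
    p_value = purrr::map_dbl(res, "p")
  )
  out$ratio_good_over_limited <- ifelse(out$mean_limited > 0,
                                        out$mean_good / out$mean_limited,
                                        NA_real_)
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  dplyr::relocate(out, "ratio_good_over_limited", .after = "mean_limited")
}

# Map quant-matrix sample columns to patient annotations.
match_samples <- function(matrix, samples) {
  check_data_frame(samples, "samples",
                   c("run_id", "patient_id", "timepoint", "response_group"))
  cols <- colnames(matrix$values)
  missing <- setdiff(cols, samples$run_id)
  if (length(missing) > 0L) {
    ms1_abort(sprintf("samples table lacks run(s): %s",
                      paste(head(missing, 5), collapse = ", ")))
  }
  samples[match(cols, samples$run_id), ]
}

#' Baseline-differential (BD) proteins
#'
#' Compares baseline protein abundances between Good- and
#' Limited-responders with a pooled two-sample t test per protein.
#' Mirroring the source analysis, no multiple-testing correction is
#' applied by default; Benjamini-Hochberg is available via
#' `adjust = "BH"`.
#'
#' @param protein_matrix A protein-level `quant_matrix` whose columns
#'   include the baseline runs.
#' @param samples Sample annotation tibble: `run_id`, `patient_id`,
#'   `timepoint` (`"baseline"`/`"post"`), `response_group`
#'   (`"Good"`/`"Limited"`).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble, one row per protein: group means, Good/Limited
#'   ratio, t statistic, p value and significance flag
#'   (`statistic_basis = "baseline_abundance"`).
#' @export
bd_differential <- function(protein_matrix, samples, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(protein_matrix, "quant_matrix"))
  check_number(alpha, "alpha", lower = 0, upper = 1, allow_zero_lower = FALSE)
  ann <- match_samples(protein_matrix, samples)
  base <- ann$timepoint == "baseline"
  if (!any(base)) ms1_abort("no baseline samples in matrix")
  values <- protein_matrix$values[, base, drop = FALSE]
  differential_table(values, ann$response_group[base] == "Good",
                     "baseline_abundance", alpha, adjust)
}

#' Treatment-induced-differential (TID) proteins
#'
#' For every patient the per-protein post/baseline abundance ratio is
#' computed (with a small epsilon floor on the denominator), then ratios
#' are compared between response groups with the pooled t test.  Every
#' patient must contribute exactly one baseline and one post run.
#'
#' @inheritParams bd_differential
#' @param ratio_epsilon Floor (in IPM) applied to the baseline abundance
#'   — and, in log mode, the post abundance — before dividing, so zero
#'   cells stay finite while nonzero ratios are untouched.
#' @param log_ratio Test log2 ratios instead of raw ratios.
#' @return A tibble as in [bd_differential()], with
#'   `statistic_basis = "post_over_baseline_ratio"`.
#' @export
tid_differential <- function(protein_matrix, samples, alpha = 0.05,
                             ratio_epsilon = 0.1, log_ratio = FALSE,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(protein_matrix, "quant_matrix"))
  check_number(alpha, "alpha", lower = 0, upper = 1, allow_zero_lower = FALSE)
  check_positive(ratio_epsilon, "ratio_epsilon")
  ann <- match_samples(protein_matrix, samples)

  counts <- table(ann$patient_id, ann$timepoint)
  bad <- rownames(counts)[counts[, "baseline"] != 1L | counts[, "post"] != 1L]
  if (length(bad) > 0L) {
    ms1_abort(sprintf("patient(s) without exactly one baseline and one post run: %s",
                      paste(bad, collapse = ", ")))
  }

  patients <- sort(unique(ann$patient_id))
  base_col <- vapply(patients, function(p) {
    which(ann$patient_id == p & ann$timepoint == "baseline")
  }, integer(1))
  post_col <- vapply(patients, function(p) {
    which(ann$patient_id == p & ann$timepoint == "post")
  }, integer(1))

  v <- protein_matrix$values
  base_v <- pmax(v[, base_col, drop = FALSE], ratio_epsilon)
  post_v <- v[, post_col, drop = FALSE]
  if (log_ratio) {
    ratios <- log2(pmax(post_v, ratio_epsilon) / base_v)
  } else {
    ratios <- post_v / base_v
  }
  colnames(ratios) <- patients
  is_good <- ann$response_group[base_col] == "Good"
  differential_table(ratios, is_good, "post_over_baseline_ratio",
                     alpha, adjust)
}

#' Classify a deamidated peptide as an N-glycosylation-site peptide
#'
#' PNGase F deglycosylation converts a glycan-bearing asparagine into
#' aspartate, observed as deamidation (+0.98402) of N.  A deamidated
#' peptide is classified as a (formerly) N-glycosylated peptide when at
#' least one of its deamidated asparagines lies in an N-X-S/T sequon
#' (X != P), evaluated in the context of the full protein sequence so
#' sequons spanning the peptide's C-terminal boundary are handled.
#'
#' @param modified_peptide Peptide in bracketed-delta notation
#'   (vectorized).
#' @param protein_sequence Full protein sequence containing the
#'   peptide's bare sequence (recycled along `modified_peptide`).
#' @return Logical vector.
#' @examples
#' classify_glycopeptide("AN[+0.98402]GSK", "MMANGSKLL")   # TRUE
#' classify_glycopeptide("AN[+0.98402]PSK", "MMANPSKLL")   # FALSE (X = P)
#' @export
classify_glycopeptide <- function(modified_peptide, protein_sequence) {
  mapply(function(pep, prot) {
    bare <- bare_peptide_sequence(pep)
    start <- as.integer(regexpr(bare, prot, fixed = TRUE))
    if (start < 1L) {
      ms1_abort(sprintf("peptide '%s' not found in protein sequence", bare))
    }
    # Positions (within the peptide) of deamidated asparagines.
    tokens <- stringr::str_match_all(pep, "([A-Za-z])(\\[([^\\]]+)\\])?")[[1]]
    residue_pos <- 0L
    deam <- integer(0)
    for (i in seq_len(nrow(tokens))) {
      residue_pos <- residue_pos + 1L
      if (!is.na(tokens[i, 4]) && tokens[i, 4] == "+0.98402") {
        deam <- c(deam, residue_pos)
      }
    }
    if (length(deam) == 0L) return(FALSE)
    prot_chars <- strsplit(prot, "")[[1]]
    any(vapply(deam, function(p) {
      pos <- start + p - 1L          # 1-based position in the protein
      if (pos + 2L > length(prot_chars)) return(FALSE)
      prot_chars[pos] == "N" &&
        prot_chars[pos + 1L] != "P" &&
        prot_chars[pos + 2L] %in% c("S", "T")
    }, logical(1)))
  }, modified_peptide, protein_sequence, USE.NAMES = FALSE)
}

#' Variant-peptide spectral-count comparison
#'
#' Compares per-patient MS/MS spectral counts of single-amino-acid
#' variant peptides between response groups with the pooled t test.
#' All-zero rows are reported (t = 0, p = 1), not dropped; rows where
#' both groups are constant at different counts are reported with an
#' infinite t and p = 0.
#'
#' @param spectral_counts Non-negative integer matrix, variant peptides
#'   x patients.
#' @param groups Character vector (`"Good"`/`"Limited"`), one per
#'   column.
#' @param alpha Significance level.
#' @param adjust `"none"` or `"BH"`.
#' @return A tibble ordered by p value
#'   (`statistic_basis = "spectral_count"`).
#' @export
variant_differential <- function(spectral_counts, groups, alpha = 0.05,
                                 adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!is.matrix(spectral_counts) || any(spectral_counts < 0) ||
      any(spectral_counts != round(spectral_counts))) {
    ms1_abort("`spectral_counts` must be a non-negative integer matrix")
  }
  if (length(groups) != ncol(spectral_counts)) {
    ms1_abort("`groups` must annotate every column")
  }
  check_number(alpha, "alpha", lower = 0, upper = 1, allow_zero_lower = FALSE)
  out <- differential_table(spectral_counts, groups == "Good",
                            "spectral_count", alpha, adjust,
                            degenerate = "infinite")
  dplyr::arrange(out, .data$p_value)
}

#' Per-patient spectral counts for variant peptides
#'
#' Tallies MS/MS identifications of variant peptides per patient from a
#' cohort's identification table (both timepoints pooled).
#'
#' @param cohort An `ms_cohort` (identifications must carry
#'   `is_variant`, `peptide_id`; runs map `run_id` to `patient_id`).
#' @return Integer matrix, variant peptides x patients.
#' @export
variant_spectral_counts <- function(cohort) {
  ids <- cohort$identifications
  runs <- cohort$runs
  check_data_frame(ids, "identifications",
                   c("run_id", "peptide_id", "is_variant"))
  vids <- ids[ids$is_variant, ]
  patients <- sort(unique(runs$patient_id))
  pep_ids <- sort(unique(vids$peptide_id))
  counts <- matrix(0L, length(pep_ids), length(patients),
                   dimnames = list(pep_ids, patients))
  if (nrow(vids) > 0L) {
    vids$patient_id <- runs$patient_id[match(vids$run_id, runs$run_id)]
    tab <- table(factor(vids$peptide_id, levels = pep_ids),
                 factor(vids$patient_id, levels = patients))
    counts[, ] <- as.integer(tab)
  }
  counts
}
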