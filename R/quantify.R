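# Library-driven MS1 extraction: 3-isotope apex summation within an RT
# window and ppm tolerance, TIC normalization to IPM, protein rollup,
# HQ-peptide filtering and quantification QC.

#' Extract a peptide's MS1 signal from one run
#'
#' Searches the run's centroided peaks within the retention-time window
#' centered on the library consensus RT.  For the monoisotopic isotope
#' (k = 0) the most intense peak within `ppm_tolerance` of the
#' theoretical m/z defines the apex scan; at that scan the three isotope
#' peaks (theoretical m/z + k * 1.00335 / z, k = 0, 1, 2) are matched at
#' the same tolerance and their intensities summed.  A missing isotope
#' contributes zero; with no monoisotopic match at all the extraction
#' returns intensity 0 and no observed ppm deviation.  Ties are broken
#' toward the most intense peak, then the smallest |ppm|, then the
#' earliest scan.
#'
#' @param peaks Peak tibble for a single run: `rt_minutes`, `mz`,
#'   `intensity`.  Peaks sharing one `rt_minutes` value form one scan.
#' @param entry A library entry (one-row tibble or list) with
#'   `theoretical_mz`, `consensus_rt` and `charge`.
#' @param rt_window_minutes Total width of the RT window (the search
#'   spans consensus RT +- half this value).
#' @param ppm_tolerance Mass-matching tolerance in parts per million.
#' @return A list: `intensity` (non-negative summed isotope intensity)
#'   and `observed_ppm` (signed ppm deviation of the monoisotopic match,
#'   `NA` when unmatched).
#' @export
extract_xic <- function(peaks, entry, rt_window_minutes = 5,
                        ppm_tolerance = 3) {
  check_data_frame(peaks, "peaks", c("rt_minutes", "mz", "intensity"))
  check_positive(rt_window_minutes, "rt_window_minutes")
  check_positive(ppm_tolerance, "ppm_tolerance")
  ord <- order(peaks$rt_minutes, peaks$mz)
  extract_xic_impl(
    rt = peaks$rt_minutes[ord], mz = peaks$mz[ord],
    intensity = peaks$intensity[ord],
    theoretical_mz = entry$theoretical_mz, charge = entry$charge,
    consensus_rt = entry$consensus_rt,
    half_window = rt_window_minutes / 2, ppm_tolerance = ppm_tolerance
  )
}

# Core extraction on rt-sorted peak vectors.
extract_xic_impl <- function(rt, mz, intensity, theoretical_mz, charge,
                             consensus_rt, half_window, ppm_tolerance) {
  n <- length(rt)
  if (n == 0L) return(list(intensity = 0, observed_ppm = NA_real_))
  i1 <- findInterval(consensus_rt - half_window, rt, left.open = TRUE) + 1L
  i2 <- findInterval(consensus_rt + half_window, rt)
  if (i1 > i2) return(list(intensity = 0, observed_ppm = NA_real_))
  idx <- i1:i2
  w_mz <- mz[idx]; w_int <- intensity[idx]; w_rt <- rt[idx]

  ppm0 <- (w_mz - theoretical_mz) / theoretical_mz * 1e6
  hit0 <- which(abs(ppm0) <= ppm_tolerance)
  if (length(hit0) == 0L) return(list(intensity = 0, observed_ppm = NA_real_))

  best0 <- hit0[order(-w_int[hit0], abs(ppm0[hit0]), w_rt[hit0])][1]
  apex_rt <- w_rt[best0]
  observed_ppm <- ppm0[best0]

  scan <- which(w_rt == apex_rt)
  total <- w_int[best0]
  for (k in 1:2) {
    target <- theoretical_mz + k * MASS_NEUTRON_SPACING / charge
    ppmk <- (w_mz[scan] - target) / target * 1e6
    hitk <- which(abs(ppmk) <= ppm_tolerance)
    if (length(hitk) > 0L) {
      bestk <- hitk[order(-w_int[scan][hitk], abs(ppmk[hitk]))][1]
      total <- total + w_int[scan][bestk]
    }
  }
  list(intensity = total, observed_ppm = observed_ppm)
}

#' TIC-normalize an intensity to ions per million (IPM)
#'
#' `IPM = intensity / TIC * 1e6`: the peptide's share of the run's total
#' ion current, in parts per million.
#'
#' @param intensity Non-negative extracted intensity (vectorized).
#' @param tic Positive total ion current of the run.
#' @return Normalized intensity in IPM.
#' @examples
#' normalize_ipm(32, 2e6)  # 16 IPM
#' @export
normalize_ipm <- function(intensity, tic) {
  if (any(!is.finite(tic)) || any(tic <= 0)) {
    ms1_abort("`tic` must be positive")
  }
  if (any(intensity < 0)) ms1_abort("`intensity` must be non-negative")
  intensity / tic * 1e6
}

#' Quantify a whole cohort against a spectral library
#'
#' Library-driven match-between-runs quantification: every library entry
#' is extracted from every run (whether or not that run carried the
#' MS/MS identification), normalized to IPM against the run's TIC, and
#' assembled into a peptide-level features x samples matrix.  Per-cell
#' identification counts and monoisotopic ppm deviations are collected
#' alongside.
#'
#' @param cohort An `ms_cohort` / `ms_runs` object, or a list with
#'   `peaks`, `runs` (with `tic`) and optionally `identifications`.
#' @param library A `spectral_library` tibble.
#' @param rt_window_minutes,ppm_tolerance Extraction parameters, see
#'   [extract_xic()].
#' @param probability_threshold Identification-probability floor used
#'   when counting per-run identifications.
#' @return A list: `peptide_matrix` (a `quant_matrix`, features keyed as
#'   `modified_peptide/charge`) and `ppm_deviations` (tibble of
#'   `feature_id`, `sample_id`, `ppm` for every matched monoisotopic
#'   peak).
#' @export
quantify_cohort <- function(cohort, library, rt_window_minutes = 5,
                            ppm_tolerance = 3,
                            probability_threshold = 0.9) {
  peaks <- cohort$peaks
  runs <- cohort$runs
  ids <- cohort$identifications
  check_data_frame(peaks, "cohort$peaks", c("run_id", "rt_minutes", "mz", "intensity"))
  check_data_frame(runs, "cohort$runs", c("run_id", "tic"))
  check_data_frame(library, "library",
                   c("modified_peptide", "charge", "theoretical_mz",
                     "consensus_rt", "protein_id"))
  if (nrow(library) == 0L) ms1_abort("`library` is empty")
  if (nrow(runs) == 0L) ms1_abort("no runs to quantify")
  if (any(!is.finite(runs$tic)) || any(runs$tic <= 0)) {
    ms1_abort("every run must carry a positive TIC")
  }
  check_positive(rt_window_minutes, "rt_window_minutes")
  check_positive(ppm_tolerance, "ppm_tolerance")

  keys <- library_key(library$modified_peptide, library$charge)
  if (anyDuplicated(keys)) ms1_abort("library keys are not unique")
  half_window <- rt_window_minutes / 2

  values <- matrix(0, nrow(library), nrow(runs),
                   dimnames = list(keys, runs$run_id))
  ppm_rows <- vector("list", nrow(runs))

  peaks_by_run <- split(peaks[c("rt_minutes", "mz", "intensity")],
                        factor(peaks$run_id, levels = runs$run_id))
  for (j in seq_len(nrow(runs))) {
    rp <- peaks_by_run[[runs$run_id[j]]]
    if (is.null(rp) || nrow(rp) == 0L) {
      ppm_rows[[j]] <- NULL
      next
    }
    ord <- order(rp$rt_minutes, rp$mz)
    rt <- rp$rt_minutes[ord]; mzv <- rp$mz[ord]; iv <- rp$intensity[ord]
    ppm_j <- rep(NA_real_, nrow(library))
    for (i in seq_len(nrow(library))) {
      res <- extract_xic_impl(
        rt, mzv, iv,
        theoretical_mz = library$theoretical_mz[i],
        charge = library$charge[i],
        consensus_rt = library$consensus_rt[i],
        half_window = half_window, ppm_tolerance = ppm_tolerance
      )
      values[i, j] <- res$intensity
      ppm_j[i] <- res$observed_ppm
    }
    matched <- which(!is.na(ppm_j))
    ppm_rows[[j]] <- tibble::tibble(
      feature_id = keys[matched], sample_id = runs$run_id[j],
      ppm = ppm_j[matched]
    )
    values[, j] <- normalize_ipm(values[, j], runs$tic[j])
  }

  id_counts <- matrix(0L, nrow(library), nrow(runs),
                      dimnames = list(keys, runs$run_id))
  if (!is.null(ids) && nrow(ids) > 0L) {
    kept <- ids[ids$probability >= probability_threshold, ]
    if (nrow(kept) > 0L) {
      tab <- table(
        factor(library_key(kept$modified_peptide, kept$charge), levels = keys),
        factor(kept$run_id, levels = runs$run_id)
      )
      id_counts[, ] <- as.integer(tab)
    }
  }

  meta <- tibble::tibble(
    feature_id = keys,
    modified_peptide = library$modified_peptide,
    bare_sequence = library$bare_sequence,
    protein_id = library$protein_id,
    charge = library$charge
  )
  list(
    peptide_matrix = new_quant_matrix(values, id_counts, "peptide", meta),
    ppm_deviations = dplyr::bind_rows(ppm_rows)
  )
}

#' Roll peptide IPM up to protein level
#'
#' Protein abundance per sample is the sum of its peptides' normalized
#' intensities in that sample; identification counts are summed the same
#' way.
#'
#' @param peptide_matrix A peptide-level `quant_matrix`.
#' @param mapping Named character vector mapping every peptide feature id
#'   to a protein id.  Defaults to the `protein_id` column of the
#'   matrix's feature metadata.
#' @return A protein-level `quant_matrix`.
#' @export
rollup_proteins <- function(peptide_matrix, mapping = NULL) {
  stopifnot(inherits(peptide_matrix, "quant_matrix"))
  if (peptide_matrix$level != "peptide") {
    ms1_abort("`peptide_matrix` must be peptide level")
  }
  keys <- rownames(peptide_matrix$values)
  if (is.null(mapping)) {
    meta <- peptide_matrix$feature_meta
    if (is.null(meta)) ms1_abort("no peptide-to-protein mapping available")
    mapping <- setNames(meta$protein_id, meta$feature_id)
  }
  unmapped <- keys[!keys %in% names(mapping) | is.na(mapping[keys])]
  if (length(unmapped) > 0L) {
    ms1_abort(sprintf(
      "unmapped peptide(s): %s",
      paste(head(unmapped, 5), collapse = ", ")
    ))
  }
  grp <- mapping[keys]
  values <- rowsum(peptide_matrix$values, grp)
  id_counts <- rowsum(peptide_matrix$id_counts, grp)
  ord <- order(rownames(values))
  mode(id_counts) <- "integer"
  new_quant_matrix(values[ord, , drop = FALSE],
                   id_counts[ord, , drop = FALSE], "protein")
}

#' Highly quantifiable (HQ) peptides
#'
#' A peptide is HQ when its normalized intensity is at least `min_ipm`
#' in every sample and it was MS/MS-identified in every sample.
#'
#' @param peptide_matrix A peptide-level `quant_matrix` with
#'   identification counts.
#' @param min_ipm IPM floor applied in every sample.
#' @param require_all_samples Require an identification in every sample
#'   (the consistent-identification half of the rule).
#' @return Character vector of qualifying peptide feature ids.
#' @export
filter_hq_peptides <- function(peptide_matrix, min_ipm = 16,
                               require_all_samples = TRUE) {
  stopifnot(inherits(peptide_matrix, "quant_matrix"))
  check_number(min_ipm, "min_ipm", lower = 0)
  ok <- apply(peptide_matrix$values >= min_ipm, 1L, all)
  if (require_all_samples) {
    ok <- ok & apply(peptide_matrix$id_counts >= 1L, 1L, all)
  }
  rownames(peptide_matrix$values)[ok]
}

#' Quantification QC report
#'
#' Summarizes monoisotopic mass deviations (mean, SD, fraction within
#' 3 ppm) and computes replicate-pair Pearson correlations on
#' log10(IPM + epsilon).  A correlation with fewer than 3 shared finite
#' features is reported as `NA`.
#'
#' @param matrix A `quant_matrix`.
#' @param ppm_deviations Tibble with a `ppm` column (as produced by
#'   [quantify_cohort()]), or `NULL`.
#' @param replicate_pairs Optional two-column data frame (`run_a`,
#'   `run_b`) naming replicate sample pairs.
#' @param epsilon Offset added before the log10 transform so zero IPM
#'   cells are admissible.
#' @return A list of class `ms_qc`: `ppm_summary` (one-row tibble:
#'   `n`, `mean_ppm`, `sd_ppm`, `frac_within_3ppm`) and `replicates`
#'   (tibble `run_a`, `run_b`, `n_features`, `r`).
#' @export
qc_report <- function(matrix, ppm_deviations = NULL,
                      replicate_pairs = NULL, epsilon = 1) {
  stopifnot(inherits(matrix, "quant_matrix"))
  check_positive(epsilon, "epsilon")

  ppm_summary <- tibble::tibble(
    n = 0L, mean_ppm = NA_real_, sd_ppm = NA_real_,
    frac_within_3ppm = NA_real_
  )
  if (!is.null(ppm_deviations) && nrow(ppm_deviations) > 0L) {
    ppm <- ppm_deviations$ppm
    if (any(!is.finite(ppm))) ms1_abort("ppm deviations must be finite")
    ppm_summary <- tibble::tibble(
      n = length(ppm), mean_ppm = mean(ppm), sd_ppm = sd(ppm),
      frac_within_3ppm = mean(abs(ppm) <= 3)
    )
  }

  replicates <- tibble::tibble(
    run_a = character(0), run_b = character(0),
    n_features = integer(0), r = numeric(0)
  )
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0L) {
    check_data_frame(replicate_pairs, "replicate_pairs", c("run_a", "run_b"))
    samples <- colnames(matrix$values)
    rows <- purrr::pmap(replicate_pairs[c("run_a", "run_b")], function(run_a, run_b) {
      if (!run_a %in% samples || !run_b %in% samples) {
        ms1_abort(sprintf("replicate pair (%s, %s) references unknown runs",
                          run_a, run_b))
      }
      a <- log10(matrix$values[, run_a] + epsilon)
      b <- log10(matrix$values[, run_b] + epsilon)
      keep <- is.finite(a) & is.finite(b)
      r <- if (sum(keep) < 3L || sd(a[keep]) == 0 || sd(b[keep]) == 0) {
        NA_real_
      } else {
        cor(a[keep], b[keep])
      }
      tibble::tibble(run_a = run_a, run_b = run_b,
                     n_features = sum(keep), r = r)
    })
    replicates <- dplyr::bind_rows(rows)
  }

  structure(list(ppm_summary = ppm_summary, replicates = replicates),
            class = "ms_qc")
}

#' @export
print.ms_qc <- function(x, ...) {
  s <- x$ppm_summary
  cat(sprintf(
    "<ms_qc> %d matched monoisotopic peaks; mean ppm %.3f (SD %.3f); %.1f%% within 3 ppm\n",
    s$n, s$mean_ppm, s$sd_ppm, 100 * s$frac_within_3ppm
  ))
  if (nrow(x$replicates) > 0L) {
    cat(sprintf("  %d replicate pair(s), median r = %.3f\n",
                nrow(x$replicates), median(x$replicates$r, na.rm = TRUE)))
  }
  invisible(x)
}
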