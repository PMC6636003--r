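# Synthetic centroided MS1 runs: isotope envelopes with ppm mass error
# and RT jitter, intermittent DDA identifications, background peaks.

#' Synthesize centroided MS1 runs for a cohort
#'
#' Turns the ground truth into one LC-MS acquisition per patient and
#' timepoint.  Each expressed peptide contributes three isotope peaks
#' spaced 1.00335/z Th, centered on its theoretical m/z perturbed by
#' ppm-scale mass error, at a retention time jittered around the
#' peptide's reference RT (apex peaks only; no chromatographic peak
#' shape).  Identification is intermittent, emulating data-dependent
#' acquisition: each peptide is identified per run with probability
#' `id_prob` (`id_prob_high` for the most intense peptides, which real
#' DDA fragments almost every run), and identified peptides carry a
#' PeptideProphet-style probability drawn uniformly from [0.9, 1].
#' Variant peptides are expressed only in their carrier patients' runs.
#'
#' @param truth `ms_truth` object from [simulate_ground_truth()].
#' @param patients Patient tibble from [simulate_patients()].
#' @param ppm_noise_sd SD of the mass error applied to each envelope, in
#'   parts per million.
#' @param rt_jitter_sd SD of the per-run retention-time jitter, minutes.
#' @param isotope_ratios Relative intensities of the M, M+1, M+2 isotope
#'   peaks.
#' @param id_prob,id_prob_high Per-run identification probabilities for
#'   ordinary and high-intensity peptides.
#' @param high_intensity_fraction Fraction of peptides (by expected
#'   intensity) treated as high-intensity for identification.
#' @param background_peaks_per_run Number of random background peaks.
#' @param background_meanlog,background_sdlog Log-normal parameters of
#'   background peak intensity.
#' @param gradient_minutes LC gradient length; all RTs fall in
#'   `[0, gradient_minutes]`.
#' @param mz_range Acquisition m/z window for background peaks.
#' @param seed Integer seed.
#' @return A list of class `ms_runs`: `runs` (run_id, patient_id,
#'   timepoint, tic), `peaks` (run_id, rt_minutes, mz, intensity; peaks
#'   sharing one rt form one scan) and `identifications` (run_id,
#'   peptide_id, modified_peptide, bare_sequence, protein_id, charge,
#'   rt_minutes, probability, variant annotation).
#' @export
simulate_runs <- function(truth, patients,
                          ppm_noise_sd = 1, rt_jitter_sd = 0.5,
                          isotope_ratios = c(1, 0.5, 0.2),
                          id_prob = 0.7, id_prob_high = 0.99,
                          high_intensity_fraction = 0.2,
                          background_peaks_per_run = 500,
                          background_meanlog = log(500),
                          background_sdlog = 1,
                          gradient_minutes = 90,
                          mz_range = c(400, 1200),
                          seed = 1) {
  if (!inherits(truth, "ms_truth")) ms1_abort("`truth` must be an `ms_truth` object")
  check_data_frame(patients, "patients", c("patient_id", "response_group"))
  check_number(ppm_noise_sd, "ppm_noise_sd", lower = 0)
  check_number(rt_jitter_sd, "rt_jitter_sd", lower = 0)
  if (length(isotope_ratios) != 3L || any(isotope_ratios <= 0)) {
    ms1_abort("`isotope_ratios` must be three positive numbers")
  }
  check_number(id_prob, "id_prob", lower = 0, upper = 1)
  check_number(id_prob_high, "id_prob_high", lower = 0, upper = 1)
  check_number(high_intensity_fraction, "high_intensity_fraction",
               lower = 0, upper = 1)
  check_number(background_peaks_per_run, "background_peaks_per_run", lower = 0)

  set.seed(as.integer(seed))
  peptides <- truth$peptides
  abundances <- truth$abundances

  # Expected intensity ranks peptides into the always-identified class.
  mean_abund <- abundances |>
    dplyr::summarise(mean_abundance = mean(.data$abundance),
                     .by = "protein_id")
  pep_expected <- dplyr::left_join(peptides, mean_abund, by = "protein_id")
  expected_intensity <- pep_expected$mean_abundance * pep_expected$response_factor
  hi_cut <- quantile(expected_intensity, 1 - high_intensity_fraction,
                     names = FALSE, type = 7)
  pep_id_prob <- ifelse(expected_intensity >= hi_cut & high_intensity_fraction > 0,
                        id_prob_high, id_prob)

  carriers <- truth$variant_carriers
  abund_key <- paste(abundances$protein_id, abundances$patient_id,
                     abundances$timepoint, sep = "\r")
  abund_lookup <- setNames(abundances$abundance, abund_key)

  run_meta <- tidyr::expand_grid(
    patient_id = patients$patient_id,
    timepoint = c("baseline", "post")
  )
  run_meta$run_id <- run_identifier(run_meta$patient_id, run_meta$timepoint)

  peak_frames <- vector("list", nrow(run_meta))
  id_frames <- vector("list", nrow(run_meta))
  tics <- numeric(nrow(run_meta))

  for (r in seq_len(nrow(run_meta))) {
    pid <- run_meta$patient_id[r]
    tp <- run_meta$timepoint[r]
    rid <- run_meta$run_id[r]

    expressed <- !peptides$is_variant |
      (peptides$peptide_id %in% carriers$peptide_id[carriers$patient_id == pid])
    pep <- peptides[expressed, ]
    p_id <- pep_id_prob[expressed]

    intensity <- abund_lookup[paste(pep$protein_id, pid, tp, sep = "\r")] *
      pep$response_factor
    rt <- pmin(pmax(pep$reference_rt + rnorm(nrow(pep), 0, rt_jitter_sd), 0),
               gradient_minutes)
    center_mz <- pep$theoretical_mz *
      (1 + rnorm(nrow(pep), 0, ppm_noise_sd) * 1e-6)

    k <- rep(0:2, each = nrow(pep))
    pep_peaks <- tibble::tibble(
      run_id = rid,
      rt_minutes = rep(rt, 3L),
      mz = rep(center_mz, 3L) + k * MASS_NEUTRON_SPACING / rep(pep$charge, 3L),
      intensity = rep(intensity, 3L) * isotope_ratios[k + 1L]
    )

    bg_n <- as.integer(background_peaks_per_run)
    bg_peaks <- tibble::tibble(
      run_id = rid,
      rt_minutes = runif(bg_n, 0, gradient_minutes),
      mz = runif(bg_n, mz_range[1], mz_range[2]),
      intensity = rlnorm(bg_n, background_meanlog, background_sdlog)
    )

    all_peaks <- dplyr::arrange(
      dplyr::bind_rows(pep_peaks, bg_peaks), .data$rt_minutes, .data$mz
    )
    peak_frames[[r]] <- all_peaks
    tics[r] <- sum(all_peaks$intensity)

    identified <- runif(nrow(pep)) < p_id
    id_frames[[r]] <- tibble::tibble(
      run_id = rid,
      peptide_id = pep$peptide_id[identified],
      modified_peptide = pep$modified_peptide[identified],
      bare_sequence = pep$bare_sequence[identified],
      protein_id = pep$protein_id[identified],
      charge = pep$charge[identified],
      rt_minutes = rt[identified],
      probability = runif(sum(identified), 0.9, 1),
      is_variant = pep$is_variant[identified],
      variant_pos = pep$variant_pos[identified],
      variant_ref = pep$variant_ref[identified],
      variant_alt = pep$variant_alt[identified]
    )
  }

  structure(
    list(
      runs = tibble::tibble(
        run_id = run_meta$run_id,
        patient_id = run_meta$patient_id,
        timepoint = run_meta$timepoint,
        tic = tics
      ),
      peaks = dplyr::bind_rows(peak_frames),
      identifications = dplyr::bind_rows(id_frames)
    ),
    class = "ms_runs"
  )
}

#' @export
print.ms_runs <- function(x, ...) {
  cat(sprintf(
    "<ms_runs> %d runs, %d peaks, %d identifications\n",
    nrow(x$runs), nrow(x$peaks), nrow(x$identifications)
  ))
  invisible(x)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_patients()],
#' [simulate_ground_truth()] and [simulate_runs()] with a single seed
#' fanned out to per-stage seeds, so any stage can be reproduced in
#' isolation.
#'
#' @param n_good,n_limited Patients per response group.
#' @param seed Integer seed for the whole cohort.
#' @param patient_args,truth_args,run_args Named lists of extra
#'   arguments forwarded to the three stage generators.
#' @return A list of class `ms_cohort` with elements `patients`,
#'   `truth`, `runs`, `peaks`, `identifications`.
#' @examples
#' cohort <- simulate_ms_cohort(n_good = 2, n_limited = 2, seed = 1,
#'   truth_args = list(n_proteins = 10, n_bd = 2, n_tid = 2,
#'                     n_glyco = 1, n_deamidated_nonsequon = 1,
#'                     n_variant = 1),
#'   run_args = list(background_peaks_per_run = 50))
#' cohort$patients
#' @export
simulate_ms_cohort <- function(n_good = 8, n_limited = 8, seed = 1,
                               patient_args = list(),
                               truth_args = list(),
                               run_args = list()) {
  patients <- do.call(simulate_patients, c(
    list(n_good = n_good, n_limited = n_limited,
         seed = stage_seed(seed, "patients")),
    patient_args
  ))
  truth <- do.call(simulate_ground_truth, c(
    list(patients = patients, seed = stage_seed(seed, "truth")),
    truth_args
  ))
  ms <- do.call(simulate_runs, c(
    list(truth = truth, patients = patients, seed = stage_seed(seed, "runs")),
    run_args
  ))
  structure(
    list(patients = patients, truth = truth, runs = ms$runs,
         peaks = ms$peaks, identifications = ms$identifications),
    class = "ms_cohort"
  )
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf(
    "<ms_cohort> %d patients (%d Good / %d Limited), %d runs, %d peaks\n",
    nrow(x$patients), sum(x$patients$response_group == "Good"),
    sum(x$patients$response_group == "Limited"),
    nrow(x$runs), nrow(x$peaks)
  ))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Persists the documented TSV dialect: `patients.tsv`, `runs.tsv`
#' (run-level metadata with TIC), `peaks.tsv` (run_id, rt_minutes, mz,
#' intensity), `identifications.tsv`, and the ground-truth tables
#' (`truth_proteins.tsv`, `truth_peptides.tsv`, `truth_abundances.tsv`,
#' `truth_variant_carriers.tsv`) when truth is attached.
#'
#' @param cohort An `ms_cohort` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  if (!inherits(cohort, "ms_cohort")) ms1_abort("`cohort` must be an `ms_cohort`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) {
    write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(cohort$patients, "patients.tsv")
  wt(cohort$runs, "runs.tsv")
  wt(cohort$peaks, "peaks.tsv")
  wt(cohort$identifications, "identifications.tsv")
  if (!is.null(cohort$truth)) {
    wt(cohort$truth$proteins, "truth_proteins.tsv")
    wt(cohort$truth$peptides, "truth_peptides.tsv")
    wt(cohort$truth$abundances, "truth_abundances.tsv")
    wt(cohort$truth$variant_carriers, "truth_variant_carriers.tsv")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort_tsv()]
#'
#' @param dir Directory containing the TSV files.
#' @return An `ms_cohort` object (with `truth` when the truth tables are
#'   present).
#' @export
read_cohort_tsv <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  }
  patients <- rd("patients.tsv")
  if (is.null(patients)) ms1_abort(sprintf("no patients.tsv under '%s'", dir))
  truth <- NULL
  if (file.exists(file.path(dir, "truth_proteins.tsv"))) {
    truth <- structure(
      list(
        proteins = rd("truth_proteins.tsv"),
        peptides = rd("truth_peptides.tsv"),
        abundances = rd("truth_abundances.tsv"),
        variant_carriers = rd("truth_variant_carriers.tsv")
      ),
      class = "ms_truth"
    )
  }
  structure(
    list(patients = patients, truth = truth, runs = rd("runs.tsv"),
         peaks = rd("peaks.tsv"), identifications = rd("identifications.tsv")),
    class = "ms_cohort"
  )
}
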