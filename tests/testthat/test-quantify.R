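# MS1 extraction, IPM normalization, rollup, HQ filter and QC.

test_that("extract_xic sums the three isotope peaks at the apex scan", {
  peaks <- tibble::tibble(
    rt_minutes = c(30, 30, 30),
    mz = c(500.0000, 500.5017, 501.0034),
    intensity = c(100, 50, 20)
  )
  entry <- list(theoretical_mz = 500.0000, charge = 2, consensus_rt = 31)
  res <- extract_xic(peaks, entry)
  expect_equal(res$intensity, 170)
  expect_equal(res$observed_ppm, 0)
})

test_that("peaks outside the ppm tolerance or RT window yield zero", {
  entry <- list(theoretical_mz = 500.0000, charge = 2, consensus_rt = 30)
  off_mass <- tibble::tibble(rt_minutes = 30, mz = 500.0030, intensity = 100)
  res <- extract_xic(off_mass, entry)   # 6 ppm off
  expect_equal(res$intensity, 0)
  expect_true(is.na(res$observed_ppm))

  off_rt <- tibble::tibble(rt_minutes = 40, mz = 500.0000, intensity = 100)
  expect_equal(extract_xic(off_rt, entry)$intensity, 0)

  empty <- tibble::tibble(rt_minutes = numeric(0), mz = numeric(0),
                          intensity = numeric(0))
  expect_equal(extract_xic(empty, entry)$intensity, 0)
  expect_error(extract_xic(off_rt, entry, rt_window_minutes = 0), "positive")
  expect_error(extract_xic(off_rt, entry, ppm_tolerance = -3), "positive")
})

test_that("extraction equals exhaustive brute-force search on random runs", {
  set.seed(101)
  for (rep in 1:25) {
    peaks <- random_peak_table(300)
    # plant a few envelopes so matches actually occur
    for (i in 1:5) {
      mz0 <- runif(1, 450, 1100)
      rt0 <- runif(1, 5, 55)
      peaks <- dplyr::bind_rows(peaks, tibble::tibble(
        rt_minutes = rt0, mz = mz0 * (1 + rnorm(1, 0, 1e-6)) +
          c(0, 1.00335 / 2, 2 * 1.00335 / 2),
        intensity = rlnorm(3, log(5000), 0.5)
      ))
      entry <- list(theoretical_mz = mz0, charge = 2,
                    consensus_rt = rt0 + runif(1, -1, 1))
      got <- extract_xic(peaks, entry)
      want <- brute_force_xic(peaks, mz0, 2, entry$consensus_rt)
      expect_identical(got$intensity, want$intensity)
      expect_identical(got$observed_ppm, want$observed_ppm)
    }
  }
})

test_that("widening the tolerance or window never loses intensity", {
  set.seed(102)
  peaks <- random_peak_table(2000, rt_range = c(20, 40), mz_range = c(499, 503))
  entry <- list(theoretical_mz = 500.5, charge = 2, consensus_rt = 30)
  base <- extract_xic(peaks, entry, 5, 3)$intensity
  expect_gte(extract_xic(peaks, entry, 5, 10)$intensity, base)
  expect_gte(extract_xic(peaks, entry, 20, 3)$intensity, base)
})

test_that("IPM follows intensity/TIC * 1e6", {
  expect_equal(normalize_ipm(32, 2e6), 16)
  expect_equal(normalize_ipm(0, 123), 0)
  expect_equal(normalize_ipm(777, 777), 1e6)
  expect_error(normalize_ipm(1, 0), "positive")
  expect_error(normalize_ipm(-1, 10), "non-negative")
})

test_that("cohort quantification fills every cell and matches between runs", {
  cohort <- tiny_cohort()
  lib <- build_library(cohort)
  q <- quantify_cohort(cohort, lib)
  qm <- q$peptide_matrix
  expect_equal(dim(qm$values), c(nrow(lib), nrow(cohort$runs)))
  expect_true(all(is.finite(qm$values)))
  expect_true(all(qm$values >= 0))
  # match-between-runs: peptides identified in only a few runs are still
  # quantified (nonzero) in runs without the identification
  ided <- qm$id_counts >= 1
  quantified <- qm$values > 0
  expect_gt(sum(quantified & !ided), 0)
})

test_that("scaling all peak intensities of one run leaves its IPM unchanged", {
  cohort <- tiny_cohort()
  lib <- build_library(cohort)
  q1 <- quantify_cohort(cohort, lib)
  scaled <- cohort
  rid <- scaled$runs$run_id[3]
  sel <- scaled$peaks$run_id == rid
  scaled$peaks$intensity[sel] <- scaled$peaks$intensity[sel] * 10
  scaled$runs$tic[scaled$runs$run_id == rid] <-
    sum(scaled$peaks$intensity[sel])
  q2 <- quantify_cohort(scaled, lib)
  expect_equal(q2$peptide_matrix$values[, rid],
               q1$peptide_matrix$values[, rid], tolerance = 1e-12)
})

test_that("noise-free extraction recovers 1.7x the true peptide intensity", {
  pats <- simulate_patients(n_good = 2, n_limited = 2, seed = 11)
  truth <- simulate_ground_truth(pats, n_proteins = 15, n_bd = 0, n_tid = 0,
                                 n_glyco = 0, n_deamidated_nonsequon = 0,
                                 n_variant = 0, biological_cv = 0, seed = 11)
  ms <- simulate_runs(truth, pats, ppm_noise_sd = 0, rt_jitter_sd = 0,
                      background_peaks_per_run = 0, id_prob = 1, seed = 11)
  cohort <- structure(
    list(patients = pats, truth = truth, runs = ms$runs, peaks = ms$peaks,
         identifications = ms$identifications),
    class = "ms_cohort"
  )
  lib <- build_library(cohort)
  q <- quantify_cohort(cohort, lib)
  abund <- truth$abundances
  for (j in seq_len(nrow(ms$runs))) {
    rid <- ms$runs$run_id[j]
    tic <- ms$runs$tic[j]
    for (i in seq_len(nrow(lib))) {
      pep <- truth$peptides[
        truth$peptides$modified_peptide == lib$modified_peptide[i], ]
      true_int <- abund$abundance[
        abund$protein_id == pep$protein_id &
          abund$patient_id == ms$runs$patient_id[j] &
          abund$timepoint == ms$runs$timepoint[j]] * pep$response_factor
      expect_equal(q$peptide_matrix$values[i, rid],
                   1.7 * true_int / tic * 1e6, tolerance = 1e-6)
    }
  }
})

test_that("protein rollup sums peptides and conserves column totals", {
  values <- matrix(c(10, 5, 2, 4, 6, 8), nrow = 3, byrow = TRUE,
                   dimnames = list(c("pepA/2", "pepB/2", "pepC/2"),
                                   c("s1", "s2")))
  qm <- ms1panel:::new_quant_matrix(values, NULL, "peptide")
  mapping <- c("pepA/2" = "P1", "pepB/2" = "P1", "pepC/2" = "P2")
  prot <- rollup_proteins(qm, mapping)
  expect_equal(prot$values["P1", "s1"], 12)       # 10 + 2
  expect_equal(prot$values["P2", ], values["pepC/2", ])  # single peptide
  expect_equal(colSums(prot$values), colSums(values))
  expect_error(rollup_proteins(qm, mapping[-1]), "unmapped")

  # conservation on a random fixture
  set.seed(103)
  rv <- matrix(rlnorm(100), 20, 5,
               dimnames = list(sprintf("p%02d/2", 1:20), sprintf("s%d", 1:5)))
  rqm <- ms1panel:::new_quant_matrix(rv, NULL, "peptide")
  rmap <- setNames(sprintf("PR%d", rep(1:5, each = 4)), rownames(rv))
  expect_equal(colSums(rollup_proteins(rqm, rmap)$values), colSums(rv))
})

test_that("HQ filter applies the 16-IPM-in-all-samples and all-ID rule", {
  values <- rbind(
    hq1 = c(16, 20, 18),
    low = c(15, 100, 100),
    noid = c(50, 60, 70)
  )
  colnames(values) <- c("s1", "s2", "s3")
  idc <- rbind(hq1 = c(1L, 1L, 1L), low = c(1L, 1L, 1L), noid = c(1L, 0L, 1L))
  colnames(idc) <- colnames(values)
  qm <- ms1panel:::new_quant_matrix(values, idc, "peptide")
  expect_identical(filter_hq_peptides(qm), "hq1")
  expect_identical(sort(filter_hq_peptides(qm, require_all_samples = FALSE)),
                   c("hq1", "noid"))
  # raising the floor can only shrink the HQ set
  set.seed(104)
  for (i in 1:20) {
    rv <- matrix(rlnorm(60, log(20), 1), 12, 5)
    rownames(rv) <- sprintf("p%02d", 1:12)
    colnames(rv) <- sprintf("s%d", 1:5)
    ridc <- matrix(rbinom(60, 1, 0.8), 12, 5, dimnames = dimnames(rv))
    mode(ridc) <- "integer"
    rqm <- ms1panel:::new_quant_matrix(rv, ridc, "peptide")
    expect_true(all(
      filter_hq_peptides(rqm, 32) %in% filter_hq_peptides(rqm, 16)
    ))
  }
})

test_that("QC reports replicate correlations and the ppm summary", {
  values <- matrix(rlnorm(40, log(100), 1), 10, 4,
                   dimnames = list(sprintf("p%d", 1:10),
                                   c("a", "a_rep", "b", "c")))
  values[, "a_rep"] <- values[, "a"]      # byte-identical replicate
  qm <- ms1panel:::new_quant_matrix(values, NULL, "peptide")
  qc <- qc_report(
    qm,
    ppm_deviations = tibble::tibble(ppm = rnorm(5000, 0, 1)),
    replicate_pairs = tibble::tibble(run_a = "a", run_b = "a_rep")
  )
  expect_equal(qc$replicates$r, 1.0)
  expect_equal(qc$ppm_summary$frac_within_3ppm, pnorm(3) - pnorm(-3),
               tolerance = 0.01)

  # anti-correlated toy vectors give r = -1 on the log scale
  anti <- matrix(c(9, 99, 999, 999, 99, 9), 3, 2,
                 dimnames = list(c("x", "y", "z"), c("u", "v")))
  aqm <- ms1panel:::new_quant_matrix(anti, NULL, "peptide")
  qc2 <- qc_report(aqm, replicate_pairs = tibble::tibble(run_a = "u",
                                                         run_b = "v"))
  expect_equal(qc2$replicates$r, -1.0)

  # too few shared features -> correlation reported absent
  tiny <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("f1", "f2"), c("r1", "r2")))
  tqm <- ms1panel:::new_quant_matrix(tiny, NULL, "peptide")
  qc3 <- qc_report(tqm, replicate_pairs = tibble::tibble(run_a = "r1",
                                                         run_b = "r2"))
  expect_true(is.na(qc3$replicates$r))
})

test_that("quant matrices tidy and round-trip through TSV", {
  cohort <- tiny_cohort()
  lib <- build_library(cohort)
  qm <- quantify_cohort(cohort, lib)$peptide_matrix
  long <- tidy(qm)
  expect_equal(nrow(long), prod(dim(qm$values)))
  stem <- file.path(withr::local_tempdir(), "pep")
  write_quant_tsv(qm, stem)
  back <- read_quant_tsv(stem, "peptide")
  expect_equal(back$values, qm$values, tolerance = 1e-12)
  expect_equal(back$id_counts, qm$id_counts)
})
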