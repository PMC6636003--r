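# Synthetic cohort generator: patients, ground truth, MS1 runs.

test_that("patient cohorts respect the 12-month response rule and determinism", {
  p <- simulate_patients(n_good = 8, n_limited = 8, seed = 1)
  expect_equal(nrow(p), 16)
  expect_equal(sum(p$survival_months >= 12), 8)
  expect_identical(
    p$response_group,
    ifelse(p$survival_months >= 12, "Good", "Limited")
  )
  expect_true(all(p$ca19_9_baseline > 0))
  expect_true(all(p$ca19_9_post > 0))
  expect_true(all(p$draw_gap_days > 0))
  # determinism
  expect_identical(p, simulate_patients(n_good = 8, n_limited = 8, seed = 1))
  # different seed moves the draws
  p2 <- simulate_patients(n_good = 8, n_limited = 8, seed = 2)
  expect_false(identical(p$survival_months, p2$survival_months))
})

test_that("truncated survival draws match a numeric-integration moment oracle", {
  p <- simulate_patients(n_good = 1000, n_limited = 1, seed = 3)
  target <- truncnorm_mean_numint(21.6, 7.0, lower = 12)
  expect_lt(abs(mean(p$survival_months[p$response_group == "Good"]) - target),
            0.5)
})

test_that("degenerate truncation and bad parameters fail explicitly", {
  expect_error(simulate_patients(survival_sd_good = 0, seed = 1), "positive")
  expect_error(
    simulate_patients(survival_mean_good = -200, survival_sd_good = 1e-3,
                      seed = 1),
    "impossible"
  )
  expect_error(simulate_patients(censoring_prob = 2, seed = 1), "range")
})

test_that("censoring switch only toggles the event flag", {
  p <- simulate_patients(n_good = 30, n_limited = 30, censoring_prob = 0.5,
                         seed = 4)
  expect_true(any(!p$event_observed))
  expect_identical(p$response_group,
                   ifelse(p$survival_months >= 12, "Good", "Limited"))
})

test_that("ground truth bookkeeping matches the request", {
  pats <- simulate_patients(n_good = 3, n_limited = 3, seed = 5)
  truth <- simulate_ground_truth(
    pats, n_proteins = 50, peptides_per_protein = 2,
    n_bd = 5, n_tid = 4, bd_log2_effect = 1.5,
    n_glyco = 4, n_deamidated_nonsequon = 2, n_variant = 3, seed = 5
  )
  expect_equal(nrow(truth$proteins), 50)
  expect_equal(sum(truth$proteins$is_bd), 5)
  expect_equal(sum(truth$proteins$is_tid), 4)
  expect_equal(sum(truth$proteins$is_bd & truth$proteins$is_tid), 0)
  expect_true(all(truth$abundances$abundance > 0))
  expect_equal(sum(truth$peptides$is_glyco_sequon), 4)

  # every variant differs from its parent at exactly one position
  vars <- truth$peptides[truth$peptides$is_variant, ]
  for (i in seq_len(nrow(vars))) {
    parent <- truth$peptides[
      truth$peptides$peptide_id == vars$parent_peptide_id[i], ]
    a <- strsplit(vars$bare_sequence[i], "")[[1]]
    b <- strsplit(parent$bare_sequence, "")[[1]]
    expect_equal(length(a), length(b))
    expect_equal(sum(a != b), 1)
    expect_equal(which(a != b), vars$variant_pos[i])
  }
})

test_that("requests exceeding the protein budget fail", {
  pats <- simulate_patients(n_good = 2, n_limited = 2, seed = 6)
  expect_error(
    simulate_ground_truth(pats, n_proteins = 10, n_bd = 8, n_tid = 5,
                          seed = 6),
    "exceeds"
  )
})

test_that("planted BD effects shift baseline group means in the truth", {
  pats <- simulate_patients(n_good = 20, n_limited = 20, seed = 7)
  truth <- simulate_ground_truth(pats, n_proteins = 30, n_bd = 6, n_tid = 0,
                                 bd_log2_effect = 2, biological_cv = 0.1,
                                 n_glyco = 0, n_deamidated_nonsequon = 0,
                                 n_variant = 0, seed = 7)
  ab <- dplyr::left_join(
    truth$abundances[truth$abundances$timepoint == "baseline", ],
    pats[c("patient_id", "response_group")], by = "patient_id"
  )
  shift <- ab |>
    dplyr::summarise(m = mean(log2(abundance)),
                     .by = c("protein_id", "response_group")) |>
    tidyr::pivot_wider(names_from = "response_group", values_from = "m") |>
    dplyr::mutate(d = Good - Limited)
  planted <- truth$proteins[truth$proteins$is_bd, ]
  observed <- shift$d[match(planted$protein_id, shift$protein_id)]
  expect_equal(observed, planted$bd_log2_effect, tolerance = 0.15)
})

test_that("runs carry consistent TIC, in-range m/z and 3-isotope envelopes", {
  cohort <- tiny_cohort()
  for (rid in cohort$runs$run_id) {
    pk <- cohort$peaks[cohort$peaks$run_id == rid, ]
    tic <- cohort$runs$tic[cohort$runs$run_id == rid]
    expect_equal(sum(pk$intensity), tic, tolerance = 1e-9)
  }
  expect_true(all(cohort$peaks$mz >= 400 - 0.01))
  # isotope envelope: noise-free single-patient run sums to 1.7x truth
  pats <- simulate_patients(n_good = 1, n_limited = 1, seed = 8)
  truth <- simulate_ground_truth(pats, n_proteins = 5, peptides_per_protein = 1,
                                 n_bd = 0, n_tid = 0, n_glyco = 0,
                                 n_deamidated_nonsequon = 0, n_variant = 0,
                                 biological_cv = 0, seed = 8)
  ms <- simulate_runs(truth, pats, ppm_noise_sd = 0, rt_jitter_sd = 0,
                      background_peaks_per_run = 0, id_prob = 1, seed = 8)
  one_run <- ms$peaks[ms$peaks$run_id == ms$runs$run_id[1], ]
  pid <- ms$runs$patient_id[1]; tp <- ms$runs$timepoint[1]
  for (i in seq_len(nrow(truth$peptides))) {
    pep <- truth$peptides[i, ]
    ab <- truth$abundances$abundance[
      truth$abundances$protein_id == pep$protein_id &
        truth$abundances$patient_id == pid &
        truth$abundances$timepoint == tp]
    envelope <- one_run[abs(one_run$rt_minutes - pep$reference_rt) < 1e-9, ]
    envelope <- envelope[envelope$mz >= pep$theoretical_mz - 1e-6, ]
    envelope <- envelope[envelope$mz <= pep$theoretical_mz +
                           2.5 * 1.00335 / pep$charge, ]
    expect_equal(sum(envelope$intensity), 1.7 * ab * pep$response_factor,
                 tolerance = 1e-9)
  }
})

test_that("identification probability 1 identifies every peptide in every run", {
  pats <- simulate_patients(n_good = 2, n_limited = 2, seed = 9)
  truth <- simulate_ground_truth(pats, n_proteins = 10, n_bd = 0, n_tid = 0,
                                 n_glyco = 0, n_deamidated_nonsequon = 0,
                                 n_variant = 0, seed = 9)
  ms <- simulate_runs(truth, pats, id_prob = 1, id_prob_high = 1,
                      background_peaks_per_run = 0, seed = 9)
  n_expected <- nrow(truth$peptides) * nrow(ms$runs)
  expect_equal(nrow(ms$identifications), n_expected)
  expect_true(all(ms$identifications$probability >= 0.9))
})

test_that("ppm mass error stays within 3 ppm at the normal-tail rate", {
  # P(|Z| < 3) ~ 0.9973 for 1-ppm Gaussian error
  pats <- simulate_patients(n_good = 4, n_limited = 4, seed = 10)
  truth <- simulate_ground_truth(pats, n_proteins = 700,
                                 peptides_per_protein = 2,
                                 n_bd = 0, n_tid = 0, n_glyco = 0,
                                 n_deamidated_nonsequon = 0, n_variant = 0,
                                 seed = 10)
  ms <- simulate_runs(truth, pats, ppm_noise_sd = 1, rt_jitter_sd = 0,
                      background_peaks_per_run = 0, seed = 10)
  # monoisotopic peaks of run 1 in truth order
  run1 <- ms$peaks[ms$peaks$run_id == ms$runs$run_id[1], ]
  # match each peptide's closest peak to theory
  devs <- vapply(seq_len(nrow(truth$peptides)), function(i) {
    pep <- truth$peptides[i, ]
    cand <- run1[abs(run1$rt_minutes - pep$reference_rt) < 1e-9, ]
    min(abs(cand$mz - pep$theoretical_mz) / pep$theoretical_mz * 1e6)
  }, numeric(1))
  expect_gt(mean(devs <= 3), 0.99)
})

test_that("variant peptides appear only in carrier patients' runs", {
  cohort <- tiny_cohort()
  carriers <- cohort$truth$variant_carriers
  ids <- cohort$identifications
  runs <- cohort$runs
  for (vid in unique(carriers$peptide_id)) {
    obs_runs <- ids$run_id[ids$peptide_id == vid]
    obs_patients <- unique(runs$patient_id[match(obs_runs, runs$run_id)])
    allowed <- carriers$patient_id[carriers$peptide_id == vid]
    expect_true(all(obs_patients %in% allowed))
  }
})

test_that("negative noise parameters are rejected", {
  cohort <- tiny_cohort()
  expect_error(
    simulate_runs(cohort$truth, cohort$patients, ppm_noise_sd = -1, seed = 1),
    "range"
  )
  expect_error(
    simulate_runs(cohort$truth, cohort$patients, rt_jitter_sd = -0.1, seed = 1),
    "range"
  )
})

test_that("cohort TSV round-trip preserves the tables", {
  cohort <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort_tsv(cohort, dir)
  back <- read_cohort_tsv(dir)
  expect_equal(back$patients$survival_months, cohort$patients$survival_months,
               tolerance = 1e-9)
  expect_equal(nrow(back$peaks), nrow(cohort$peaks))
  expect_equal(back$runs$tic, cohort$runs$tic, tolerance = 1e-9)
  expect_equal(nrow(back$truth$peptides), nrow(cohort$truth$peptides))
})
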