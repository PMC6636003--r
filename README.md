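# ms1panel

Label-free plasma proteomics for chemotherapy-response prediction:
spectral-library-driven MS1 quantification of paired pre/post-treatment
plasma runs, differential protein discovery, and composite-biomarker
evaluation with survival stratification.

## Who this is for

Proteomics and biomarker researchers who stratify cancer patients by
treatment response — here, pancreatic-cancer patients split into
**Good-responders** (overall survival ≥ 12 months) and
**Limited-responders** (< 12 months) — and want a tested, reproducible
implementation of the full analysis chain from centroided MS1 peaks to
a Kaplan–Meier comparison of biomarker-stratified groups.  Because
clinical MS cohorts are rarely deposited, the package also ships a
fully specified synthetic cohort generator (patients, ground-truth
proteome, MS1 runs with isotope envelopes and ppm mass error,
intermittent DDA identifications), so the whole pipeline runs and is
testable without any download.

## The method

1. **Spectral library** — every peptide identified in *any* run at
   PeptideProphet-style probability ≥ 0.9 becomes a library entry keyed
   by (modified sequence, charge), with theoretical precursor m/z and
   median consensus retention time.
2. **MS1 match-between-runs quantification** — for each entry and each
   run, the three isotope peaks (m/z + k·1.00335/z, k = 0,1,2) are
   matched within 3 ppm inside a 5-min RT window and summed at the apex
   scan.  Intensities are normalized to ions per million:

   `IPM = peptide intensity / TIC × 1e6`

   and protein abundance is the sum of its peptides' IPM.  Peptides with
   ≥ 16 IPM identified in all samples are flagged *highly quantifiable*
   (HQ).
3. **Differential analysis** — pooled two-sample t tests (α = 0.05)
   find **BD** proteins (baseline abundance differs between response
   groups) and **TID** proteins (post/baseline ratio differs);
   deamidated peptides in an N-X-S/T sequon (X ≠ P) are classified as
   deglycosylated N-glycopeptides; single-amino-acid variant peptides
   are compared by spectral counts.  PCA and hierarchical clustering
   provide the sample- and feature-level views.
4. **Biomarker panel** — a binary logistic model combines top BD
   proteins with CA 19-9; its ROC curve is summarized by the
   pair-counting AUC and two operating points (sensitivity at 90%
   specificity, specificity at 90% sensitivity); the score cutoff
   maximizes specificity subject to sensitivity ≥ 0.9 and splits
   patients into Biomarker-positive/negative, compared by Kaplan–Meier
   and log-rank.  A leave-one-out scan quantifies each patient's
   influence on the panel AUC.

## Worked example

```r
library(ms1panel)
library(dplyr)

cohort <- simulate_ms_cohort(seed = 42)
cohort
#> <ms_cohort> 16 patients (8 Good / 8 Limited), 32 runs, 73690 peaks

lib      <- build_library(cohort)                     # probability >= 0.9
quant    <- quantify_cohort(cohort, lib)              # 5 min / 3 ppm MBR
proteins <- rollup_proteins(quant$peptide_matrix)
proteins
#> <quant_matrix> protein level: 200 features x 32 samples

samples <- left_join(cohort$runs,
                     select(cohort$patients, patient_id, response_group),
                     by = "patient_id")
bd <- bd_differential(proteins, samples)
arrange(bd, p_value) |> head(3)
#> # A tibble: 3 x 9
#>   feature_id mean_good mean_limited ratio_good_over_limited ...
#> 1 PROT115        9729.        3421.                   2.84
#> 2 PROT178        7145.       20576.                   0.347
#> 3 PROT105       16892.        6177.                   2.73
sum(bd$significant)
#> [1] 18      # 10 planted BD proteins plus null proteins at ~alpha
```

The top four BD proteins plus baseline CA 19-9 form the panel:

```r
panel_ids <- arrange(bd, p_value)$feature_id[1:4]
baseline  <- filter(samples, timepoint == "baseline")
markers   <- as_tibble(t(proteins$values[panel_ids, baseline$run_id]))
markers$patient_id <- baseline$patient_id
markers$CA19_9 <- cohort$patients$ca19_9_baseline[
  match(markers$patient_id, cohort$patients$patient_id)]
labels <- cohort$patients$response_group[
  match(markers$patient_id, cohort$patients$patient_id)]

model <- fit_logistic_panel(markers, labels)   # score = P(Limited)
roc   <- roc_curve(predict(model, markers), labels, "Limited")
roc
#> <roc_result> AUC 1.000 (8 pos / 8 neg, positive = 'Limited');
#>              sens@spec90 1.00, spec@sens90 1.00

strat <- stratify_patients(model, derive_cutoff(roc, 0.9), markers)
surv  <- left_join(strat,
                   select(cohort$patients, patient_id, survival_months,
                          event_observed),
                   by = "patient_id")
compare_survival(surv)
#> <survival_comparison>
#>   Biomarker-negative: n = 8, median 23.9 (95% CI 21.0-NA)
#>   Biomarker-positive: n = 8, median 6.8 (95% CI 5.8-NA)
#>   log-rank chi2 = 16.94, p = 3.853e-05
```

With the default planted effects the in-sample panel separates the
response groups completely (AUC 1.0) and the stratified survival
medians differ by ~17 months — the synthetic cohort is built so the
planted biology is recoverable; the interesting guarantees (type-I
error calibration, power, AUC/operating-point correctness, estimator
behavior) live in the test suite.  `autoplot()` methods exist for ROC
curves, PCA scores, survival comparisons and clustered heatmaps, and
`tidy()`/`glance()` for every fitted object.

The same chain runs as one call — `run_pipeline(list(seed = 42))` —
writing TSV/JSON artifacts and a manifest; a thin command-line wrapper
lives at `inst/scripts/ms1panel`.

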