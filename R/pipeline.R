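# End-to-end pipeline: simulate -> build-library -> quantify ->
# differential -> biomarker -> survival, with a validated config and a
# reproducibility manifest.

PIPELINE_DEFAULTS <- list(
  seed = 1L,
  n_good = 8L, n_limited = 8L, stage = "IV",
  n_proteins = 200L, peptides_per_protein = 3L,
  n_bd = 10L, n_tid = 8L,
  bd_log2_effect = 1.5, tid_log2_effect = 1.5,
  n_glyco = 10L, n_deamidated_nonsequon = 5L, n_variant = 5L,
  background_peaks_per_run = 500L, id_prob = 0.7,
  rt_window = 5, ppm = 3, min_ipm = 16, probability_threshold = 0.9,
  alpha = 0.05, sens_floor = 0.9, panel_size = 4L,
  include_ca19_9 = TRUE,
  out_dir = "ms1panel_output"
)

PIPELINE_RANGES <- list(
  n_good = c(1, Inf), n_limited = c(1, Inf),
  n_proteins = c(1, Inf), peptides_per_protein = c(1, Inf),
  n_bd = c(0, Inf), n_tid = c(0, Inf),
  n_glyco = c(0, Inf), n_deamidated_nonsequon = c(0, Inf),
  n_variant = c(0, Inf),
  background_peaks_per_run = c(0, Inf), id_prob = c(0, 1),
  rt_window = c(1e-9, Inf), ppm = c(1e-9, Inf), min_ipm = c(0, Inf),
  probability_threshold = c(0, 1),
  alpha = c(1e-12, 1 - 1e-12), sens_floor = c(0, 1),
  panel_size = c(1, Inf)
)

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path, fills in every default,
#' range-checks all numeric parameters, and rejects unknown keys (typo
#' safety).  All problems are reported together, not first-only.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @return A fully defaulted list of class `pipeline_config`.
#' @examples
#' cfg <- validate_config(list(n_proteins = 50, seed = 7))
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) ms1_abort("`config` must be a named list or YAML path")
  errors <- character(0)
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    errors <- c(errors, sprintf("unknown key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS,
                           config[setdiff(names(config), unknown)])
  for (key in names(PIPELINE_RANGES)) {
    v <- cfg[[key]]
    rng <- PIPELINE_RANGES[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < rng[1] || v > rng[2]) {
      errors <- c(errors, sprintf(
        "`%s` = %s is outside its allowed range [%g, %g]",
        key, format(v), rng[1], rng[2]
      ))
    }
  }
  if (!cfg$stage %in% c("III", "IV")) {
    errors <- c(errors, sprintf("`stage` must be 'III' or 'IV', got '%s'",
                                cfg$stage))
  }
  if (is.numeric(cfg$n_bd) && is.numeric(cfg$n_tid) &&
      is.numeric(cfg$n_proteins) && cfg$n_bd + cfg$n_tid > cfg$n_proteins) {
    errors <- c(errors, "`n_bd` + `n_tid` exceeds `n_proteins`")
  }
  if (length(errors) > 0L) {
    ms1_abort(paste(c("invalid pipeline config:", errors), collapse = "\n  - "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order — cohort simulation, spectral-library
#' construction, MS1 quantification with QC, BD/TID/variant differential
#' analysis, biomarker-panel evaluation, and survival stratification —
#' writing each stage's artifacts under `config$out_dir` and a manifest
#' sufficient to re-run bit-identically.  Any stage failure aborts with
#' the stage name and cause; artifacts already written are retained.
#'
#' The panel markers are the `panel_size` most significant BD proteins
#' (baseline IPM), optionally joined by baseline CA 19-9.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a
#'   list/YAML path, validated on the way in).
#' @return The manifest (a list), invisibly written as
#'   `manifest.json`: seed, parameter echo, per-stage row counts and
#'   output files, plus headline results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ms1_abort(sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)))
    })
  }
  # The parameter echo deliberately omits the output path, so two runs of
  # one configuration are byte-identical wherever they are written.
  params <- unclass(cfg)
  params$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("ms1panel")),
    seed = cfg$seed,
    parameters = params,
    stages = list()
  )

  # --- simulate ----------------------------------------------------------
  cohort <- run_stage("simulate", {
    simulate_ms_cohort(
      n_good = cfg$n_good, n_limited = cfg$n_limited, seed = cfg$seed,
      patient_args = list(stage = cfg$stage),
      truth_args = list(
        n_proteins = cfg$n_proteins,
        peptides_per_protein = cfg$peptides_per_protein,
        n_bd = cfg$n_bd, n_tid = cfg$n_tid,
        bd_log2_effect = cfg$bd_log2_effect,
        tid_log2_effect = cfg$tid_log2_effect,
        n_glyco = cfg$n_glyco,
        n_deamidated_nonsequon = cfg$n_deamidated_nonsequon,
        n_variant = cfg$n_variant
      ),
      run_args = list(
        background_peaks_per_run = cfg$background_peaks_per_run,
        id_prob = cfg$id_prob
      )
    )
  })
  run_stage("simulate", write_cohort_tsv(cohort, file.path(out, "cohort")))
  manifest$stages$simulate <- list(
    n_patients = nrow(cohort$patients), n_runs = nrow(cohort$runs),
    n_peaks = nrow(cohort$peaks),
    n_identifications = nrow(cohort$identifications)
  )

  # --- build-library -----------------------------------------------------
  library_tbl <- run_stage("build-library", {
    lib <- build_library(cohort, cfg$probability_threshold)
    write_library_tsv(lib, file.path(out, "library.tsv"))
    lib
  })
  manifest$stages$build_library <- list(n_entries = nrow(library_tbl))

  # --- quantify ----------------------------------------------------------
  quant <- run_stage("quantify", {
    q <- quantify_cohort(cohort, library_tbl,
                         rt_window_minutes = cfg$rt_window,
                         ppm_tolerance = cfg$ppm,
                         probability_threshold = cfg$probability_threshold)
    write_quant_tsv(q$peptide_matrix, file.path(out, "peptide_matrix"))
    q
  })
  protein_matrix <- run_stage("quantify", {
    pm <- rollup_proteins(quant$peptide_matrix)
    write_quant_tsv(pm, file.path(out, "protein_matrix"))
    pm
  })
  hq <- filter_hq_peptides(quant$peptide_matrix, min_ipm = cfg$min_ipm)
  qc <- qc_report(quant$peptide_matrix, quant$ppm_deviations)
  run_stage("quantify", {
    writeLines(hq, file.path(out, "hq_peptides.txt"))
    jsonlite::write_json(
      list(ppm_summary = qc$ppm_summary, n_hq_peptides = length(hq)),
      file.path(out, "qc_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  })
  manifest$stages$quantify <- list(
    n_peptides = nrow(quant$peptide_matrix$values),
    n_proteins = nrow(protein_matrix$values),
    n_samples = ncol(protein_matrix$values),
    n_hq_peptides = length(hq),
    frac_within_3ppm = qc$ppm_summary$frac_within_3ppm,
    mean_ppm = qc$ppm_summary$mean_ppm,
    sd_ppm = qc$ppm_summary$sd_ppm,
    n_ppm_matches = qc$ppm_summary$n
  )

  # --- differential ------------------------------------------------------
  samples <- dplyr::left_join(
    cohort$runs,
    dplyr::select(cohort$patients, "patient_id", "response_group"),
    by = "patient_id"
  )
  diff_res <- run_stage("differential", {
    bd <- bd_differential(protein_matrix, samples, alpha = cfg$alpha)
    tid <- tid_differential(protein_matrix, samples, alpha = cfg$alpha)
    counts <- variant_spectral_counts(cohort)
    var_groups <- cohort$patients$response_group[
      match(colnames(counts), cohort$patients$patient_id)
    ]
    variants <- if (nrow(counts) > 0L) {
      variant_differential(counts, var_groups, alpha = cfg$alpha)
    } else {
      tibble::tibble()
    }
    write.table(bd, file.path(out, "bd_proteins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(tid, file.path(out, "tid_proteins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(variants, file.path(out, "variant_peptides.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(bd = bd, tid = tid, variants = variants)
  })
  run_stage("differential", {
    baseline <- samples$timepoint == "baseline"
    sig_bd <- diff_res$bd$feature_id[diff_res$bd$significant]
    if (length(sig_bd) >= 2L) {
      pca <- pca_transform(
        t(protein_matrix$values[sig_bd, baseline, drop = FALSE]),
        n_components = 2, log_transform = TRUE
      )
      write.table(tidy(pca), file.path(out, "pca_bd_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      clust <- cluster_features(
        protein_matrix$values[sig_bd, baseline, drop = FALSE]
      )
      write.table(clust$heatmap, file.path(out, "heatmap_bd.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  })
  manifest$stages$differential <- list(
    n_bd_significant = sum(diff_res$bd$significant),
    n_tid_significant = sum(diff_res$tid$significant),
    n_variant_tested = nrow(diff_res$variants)
  )

  # --- biomarker ---------------------------------------------------------
  biomarker <- run_stage("biomarker", {
    panel_proteins <- diff_res$bd |>
      dplyr::arrange(.data$p_value, .data$feature_id) |>
      head(cfg$panel_size) |>
      dplyr::pull("feature_id")
    baseline_runs <- samples[samples$timepoint == "baseline", ]
    markers <- tibble::as_tibble(
      t(protein_matrix$values[panel_proteins, baseline_runs$run_id,
                              drop = FALSE])
    )
    markers$patient_id <- baseline_runs$patient_id
    if (isTRUE(cfg$include_ca19_9)) {
      markers$CA19_9 <- cohort$patients$ca19_9_baseline[
        match(markers$patient_id, cohort$patients$patient_id)
      ]
    }
    labels <- cohort$patients$response_group[
      match(markers$patient_id, cohort$patients$patient_id)
    ]
    model <- fit_logistic_panel(markers, labels)
    scores <- predict(model, markers)
    roc <- roc_curve(scores, labels, "Limited")
    cutoff <- derive_cutoff(roc, sens_at_least = cfg$sens_floor)
    strat <- stratify_patients(model, cutoff, markers)
    orientations <- roc_both_orientations(scores, labels)
    write.table(tidy(roc), file.path(out, "roc_points.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(strat, file.path(out, "stratification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(
        panel = c(panel_proteins,
                  if (isTRUE(cfg$include_ca19_9)) "CA19_9"),
        coefficients = as.list(c(`(Intercept)` = model$intercept,
                                 model$coefficients)),
        auc = roc$auc, sens_at_spec90 = roc$sens_at_spec90,
        spec_at_sens90 = roc$spec_at_sens90, cutoff = cutoff,
        orientations = orientations
      ),
      file.path(out, "panel_summary.json"), auto_unbox = TRUE, digits = NA
    )
    list(model = model, roc = roc, cutoff = cutoff, strat = strat,
         labels = labels,
         panel_proteins = c(panel_proteins,
                            if (isTRUE(cfg$include_ca19_9)) "CA19_9"))
  })
  manifest$stages$biomarker <- list(
    panel = biomarker$panel_proteins,
    auc = biomarker$roc$auc,
    sens_at_spec90 = biomarker$roc$sens_at_spec90,
    spec_at_sens90 = biomarker$roc$spec_at_sens90,
    cutoff = biomarker$cutoff,
    n_biomarker_positive = sum(
      biomarker$strat$biomarker_status == "Biomarker-positive"
    )
  )

  # --- survival ----------------------------------------------------------
  surv <- run_stage("survival", {
    dat <- dplyr::left_join(
      biomarker$strat,
      dplyr::select(cohort$patients, "patient_id", "survival_months",
                    "event_observed"),
      by = "patient_id"
    )
    if (length(unique(dat$biomarker_status)) == 2L) {
      cmp <- compare_survival(dat)
      write.table(tidy(cmp), file.path(out, "km_curves.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(medians = cmp$medians, logrank_chi2 = cmp$logrank_chi2,
             logrank_p = cmp$logrank_p),
        file.path(out, "survival_summary.json"), auto_unbox = TRUE,
        digits = NA
      )
      cmp
    } else {
      warn("all patients fell in one biomarker stratum; survival comparison skipped")
      NULL
    }
  })
  manifest$stages$survival <- if (!is.null(surv)) {
    list(logrank_chi2 = surv$logrank_chi2, logrank_p = surv$logrank_p,
         medians = surv$medians)
  } else {
    list(skipped = "single stratum")
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Human-readable pipeline report
#'
#' Summarizes a completed pipeline run (from its manifest) as Markdown:
#' cohort size, library and matrix dimensions, QC, BD/TID counts, panel
#' operating points and stratified survival medians.
#'
#' @param out_dir Pipeline output directory containing `manifest.json`.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly.
#' @export
pipeline_report <- function(out_dir, path = NULL) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    ms1_abort(sprintf("no manifest.json under '%s'", out_dir))
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  s <- m$stages
  lines <- c(
    "# Pipeline report",
    "",
    sprintf("- seed: %s", m$seed),
    sprintf("- patients: %d (%d runs, %d identifications)",
            s$simulate$n_patients, s$simulate$n_runs,
            s$simulate$n_identifications),
    sprintf("- spectral library entries: %d", s$build_library$n_entries),
    sprintf("- quantified: %d peptides -> %d proteins across %d samples",
            s$quantify$n_peptides, s$quantify$n_proteins,
            s$quantify$n_samples),
    sprintf("- HQ peptides (>= %g IPM, identified in all samples): %d",
            m$parameters$min_ipm, s$quantify$n_hq_peptides),
    sprintf("- monoisotopic matches within 3 ppm: %.1f%%",
            100 * s$quantify$frac_within_3ppm),
    sprintf("- BD proteins significant at alpha = %g: %d",
            m$parameters$alpha, s$differential$n_bd_significant),
    sprintf("- TID proteins significant: %d",
            s$differential$n_tid_significant),
    sprintf("- panel (%s): AUC %.3f, sens@spec90 %.2f, spec@sens90 %.2f",
            paste(s$biomarker$panel, collapse = " + "),
            s$biomarker$auc, s$biomarker$sens_at_spec90,
            s$biomarker$spec_at_sens90),
    sprintf("- biomarker-positive patients: %d / %d",
            s$biomarker$n_biomarker_positive, s$simulate$n_patients)
  )
  if (is.null(s$survival$skipped)) {
    med <- s$survival$medians
    lines <- c(lines, sprintf(
      "- survival: %s median %.1f vs %s median %.1f months; log-rank p = %.4g",
      med$group[1], med$median[1], med$group[2], med$median[2],
      s$survival$logrank_p
    ))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
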