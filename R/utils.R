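# Internal helpers shared across modules.

# Stop with a consistent error class so callers can test failures precisely.
ms1_abort <- function(msg, class = "ms1panel_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ms1_abort(sprintf("`%s` must be a single finite number", name))
  }
  ok_low <- if (allow_zero_lower) x >= lower else x > lower
  if (!ok_low || x > upper) {
    if (!allow_zero_lower && lower == 0) {
      ms1_abort(sprintf("`%s` must be positive, got %g", name, x))
    }
    ms1_abort(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name, lower = 0, allow_zero_lower = FALSE)
}

check_data_frame <- function(x, name, cols) {
  if (!is.data.frame(x)) {
    ms1_abort(sprintf("`%s` must be a data frame", name))
  }
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0L) {
    ms1_abort(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(x)
}

# Fan a single pipeline seed out to per-stage seeds with fixed offsets so a
# stage can be re-run in isolation and still reproduce its output.  Offsets
# are kept small so user seeds up to ~2e9 stay within R's integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(
    patients = 101L, truth = 211L, runs = 307L, library = 401L,
    quantify = 503L, differential = 601L, biomarker = 701L, survival = 809L
  )
  if (!stage %in% names(offsets)) {
    ms1_abort(sprintf("unknown pipeline stage '%s'", stage))
  }
  as.integer((as.numeric(seed) + offsets[[stage]]) %% .Machine$integer.max)
}

# Deterministic lowercase run identifier: <patient>_<timepoint>.
run_identifier <- function(patient_id, timepoint) {
  paste0(patient_id, "_", timepoint)
}
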