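# Cohort-combined spectral library built from filtered identifications.

#' Build a cohort-combined spectral library
#'
#' Collapses filtered peptide identifications from all runs into one
#' library entry per (modified peptide, charge) pair.  Only
#' identifications at or above the probability threshold contribute
#' (0.9 by default, matching PeptideProphet filtering at 1% FDR).  The
#' consensus retention time is the median of contributing identification
#' RTs; the precursor m/z is always computed from the theoretical
#' monoisotopic mass, never averaged from observations, so downstream
#' ppm-deviation QC is anchored to theory.
#'
#' @param identifications A tibble of identifications with columns
#'   `run_id`, `modified_peptide`, `bare_sequence`, `protein_id`,
#'   `charge`, `rt_minutes`, `probability` — or an `ms_cohort` /
#'   `ms_runs` object carrying one.
#' @param probability_threshold Minimum identification probability.
#' @return A tibble of class `spectral_library`, one row per
#'   (modified_peptide, charge): `modified_peptide`, `bare_sequence`,
#'   `protein_id`, `charge`, `theoretical_mz`, `consensus_rt`, `n_ids`
#'   (number of distinct runs contributing).
#' @examples
#' cohort <- simulate_ms_cohort(n_good = 2, n_limited = 2, seed = 1,
#'   truth_args = list(n_proteins = 10, n_bd = 0, n_tid = 0, n_glyco = 0,
#'                     n_deamidated_nonsequon = 0, n_variant = 0),
#'   run_args = list(background_peaks_per_run = 0))
#' lib <- build_library(cohort)
#' head(lib)
#' @export
build_library <- function(identifications, probability_threshold = 0.9) {
  if (inherits(identifications, c("ms_cohort", "ms_runs"))) {
    identifications <- identifications$identifications
  }
  check_data_frame(identifications, "identifications",
                   c("run_id", "modified_peptide", "bare_sequence",
                     "protein_id", "charge", "rt_minutes", "probability"))
  check_number(probability_threshold, "probability_threshold",
               lower = 0, upper = 1)
  if (nrow(identifications) == 0L) {
    ms1_abort("empty library: no identifications supplied")
  }

  kept <- dplyr::filter(identifications,
                        .data$probability >= probability_threshold)
  if (nrow(kept) == 0L) {
    ms1_abort(sprintf(
      "empty library: no identification reaches probability %g",
      probability_threshold
    ))
  }

  lib <- kept |>
    dplyr::summarise(
      bare_sequence = .data$bare_sequence[1],
      protein_id = .data$protein_id[1],
      consensus_rt = median(.data$rt_minutes),
      n_ids = dplyr::n_distinct(.data$run_id),
      .by = c("modified_peptide", "charge")
    ) |>
    dplyr::mutate(
      theoretical_mz = precursor_mz(
        peptide_monoisotopic_mass(.data$modified_peptide), .data$charge
      )
    ) |>
    dplyr::select("modified_peptide", "bare_sequence", "protein_id",
                  "charge", "theoretical_mz", "consensus_rt", "n_ids") |>
    dplyr::arrange(.data$modified_peptide, .data$charge)

  class(lib) <- c("spectral_library", class(lib))
  lib
}

# Stable feature key for a library entry.
library_key <- function(modified_peptide, charge) {
  paste0(modified_peptide, "/", charge)
}

#' Write / read a spectral library as TSV
#'
#' Round-trip is lossless at full double precision (m/z and RT are
#' serialized with 15 significant digits).
#'
#' @param library A `spectral_library` tibble.
#' @param path File path.
#' @return `write_library_tsv()` returns `path` invisibly;
#'   `read_library_tsv()` returns the `spectral_library` tibble.
#' @export
write_library_tsv <- function(library, path) {
  check_data_frame(library, "library",
                   c("modified_peptide", "bare_sequence", "protein_id",
                     "charge", "theoretical_mz", "consensus_rt", "n_ids"))
  out <- as.data.frame(library)
  for (col in c("theoretical_mz", "consensus_rt")) {
    out[[col]] <- sprintf("%.15g", out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  lib <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
  lib$theoretical_mz <- as.numeric(lib$theoretical_mz)
  lib$consensus_rt <- as.numeric(lib$consensus_rt)
  lib$charge <- as.integer(lib$charge)
  lib$n_ids <- as.integer(lib$n_ids)
  class(lib) <- c("spectral_library", class(lib))
  lib
}
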