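# Peptide monoisotopic masses and precursor m/z.
#
# Modified sequences use bracketed monoisotopic mass deltas to five
# decimals, e.g. "AC[+57.02146]DK".  Fixed carbamidomethylation of
# cysteine is always written explicitly, so the calculator computes
# exactly what the sequence notates.

MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276
# Average spacing between successive isotope peaks of a peptide, in Da.
MASS_NEUTRON_SPACING <- 1.00335

# Supported variable/fixed modifications: bracketed delta -> (name, residue).
MODIFICATION_REGISTRY <- tibble::tibble(
  delta_token = c("+57.02146", "+15.99491", "+0.98402"),
  delta = c(57.02146, 15.99491, 0.98402),
  name = c("carbamidomethyl", "oxidation", "deamidation"),
  residue = c("C", "M", "N")
)

#' Monoisotopic mass of a (modified) peptide
#'
#' Computes the neutral monoisotopic mass of a peptide written with the
#' package's bracketed-delta notation: the sum of the monoisotopic residue
#' masses, one water, and every bracketed modification delta.  Only the
#' three modifications used throughout the pipeline are accepted:
#' carbamidomethyl-C (`[+57.02146]`), oxidation-M (`[+15.99491]`) and
#' deamidation-N (`[+0.98402]`).  Fixed carbamidomethylation must be
#' written explicitly.
#'
#' @param modified_peptide Character vector of peptide sequences in
#'   bracketed-delta notation (one-letter amino-acid codes).
#' @return Numeric vector of neutral monoisotopic masses in Daltons.
#' @examples
#' peptide_monoisotopic_mass("GG")
#' peptide_monoisotopic_mass("AC[+57.02146]DK")
#' @export
peptide_monoisotopic_mass <- function(modified_peptide) {
  if (!is.character(modified_peptide) || length(modified_peptide) < 1L) {
    ms1_abort("`modified_peptide` must be a character vector")
  }
  vapply(modified_peptide, peptide_mass_one, numeric(1), USE.NAMES = FALSE)
}

peptide_mass_one <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) {
    ms1_abort("empty peptide sequence")
  }
  # Tokenize into residues and bracketed deltas.
  tokens <- stringr::str_match_all(seq, "([A-Za-z])|\\[([^\\]]+)\\]")[[1]]
  consumed <- sum(nchar(tokens[, 1]))
  if (consumed != nchar(seq)) {
    ms1_abort(sprintf("unparseable characters in peptide '%s'", seq))
  }
  residues <- tokens[, 2]
  deltas <- tokens[, 3]
  mass <- MASS_WATER
  last_residue <- NA_character_
  n_res <- 0L
  for (i in seq_len(nrow(tokens))) {
    if (!is.na(residues[i])) {
      aa <- toupper(residues[i])
      if (!aa %in% names(MONOISOTOPIC_RESIDUE_MASS)) {
        ms1_abort(sprintf("unknown residue '%s' in peptide '%s'", residues[i], seq))
      }
      mass <- mass + MONOISOTOPIC_RESIDUE_MASS[[aa]]
      last_residue <- aa
      n_res <- n_res + 1L
    } else {
      tok <- deltas[i]
      hit <- match(tok, MODIFICATION_REGISTRY$delta_token)
      if (is.na(hit)) {
        ms1_abort(sprintf("unsupported modification '[%s]' in peptide '%s'", tok, seq))
      }
      if (is.na(last_residue)) {
        ms1_abort(sprintf("modification '[%s]' precedes any residue in '%s'", tok, seq))
      }
      if (last_residue != MODIFICATION_REGISTRY$residue[hit]) {
        ms1_abort(sprintf(
          "modification '[%s]' (%s) is only valid on %s, found on %s in '%s'",
          tok, MODIFICATION_REGISTRY$name[hit],
          MODIFICATION_REGISTRY$residue[hit], last_residue, seq
        ))
      }
      mass <- mass + MODIFICATION_REGISTRY$delta[hit]
    }
  }
  if (n_res == 0L) ms1_abort(sprintf("peptide '%s' contains no residues", seq))
  mass
}

#' Precursor m/z from neutral mass and charge
#'
#' Standard electrospray convention: `(mass + z * 1.007276) / z`.
#'
#' @param mass Neutral monoisotopic mass in Daltons (vectorized).
#' @param charge Positive integer charge state (vectorized).
#' @return Precursor m/z in Thomson.
#' @examples
#' precursor_mz(132.05349, 1)
#' @export
precursor_mz <- function(mass, charge) {
  if (!is.numeric(mass) || !is.numeric(charge)) {
    ms1_abort("`mass` and `charge` must be numeric")
  }
  if (any(!is.finite(charge)) || any(charge < 1) || any(charge != round(charge))) {
    ms1_abort("`charge` must be a positive integer")
  }
  (mass + charge * MASS_PROTON) / charge
}

# Strip bracketed modifications, giving the bare sequence.
bare_peptide_sequence <- function(modified_peptide) {
  toupper(stringr::str_remove_all(modified_peptide, "\\[[^\\]]+\\]"))
}
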