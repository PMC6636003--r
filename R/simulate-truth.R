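# Ground-truth proteome: proteins, tryptic peptides, planted BD/TID
# effects, sequon glycopeptides and single-residue variant peptides.

# Residues used when drawing random tryptic peptides.  Cysteine is drawn
# rarely and always notated with its fixed carbamidomethyl delta.
PEPTIDE_ALPHABET <- c(
  "G", "A", "S", "P", "V", "T", "L", "I", "N", "D",
  "Q", "E", "M", "H", "F", "Y", "W", "C"
)
PEPTIDE_ALPHABET_W <- c(rep(1, 17), 0.3)

random_tryptic_peptide <- function(min_len = 8, max_len = 16) {
  len <- sample(min_len:max_len, 1)
  body <- sample(PEPTIDE_ALPHABET, len - 1L, replace = TRUE,
                 prob = PEPTIDE_ALPHABET_W)
  c(body, sample(c("K", "R"), 1))
}

# Notate a residue vector as a modified sequence: fixed carbamidomethyl on
# every C, plus optional deamidation at given N positions.
notate_peptide <- function(residues, deamidated_at = integer(0)) {
  out <- residues
  out[out == "C"] <- "C[+57.02146]"
  for (i in deamidated_at) {
    stopifnot(residues[i] == "N")
    out[i] <- "N[+0.98402]"
  }
  paste(out, collapse = "")
}

# Pick a charge placing the precursor within the acquisition window.
charge_in_range <- function(mass, mz_range) {
  for (z in c(2L, 3L, 1L, 4L)) {
    mz <- precursor_mz(mass, z)
    if (mz >= mz_range[1] && mz <= mz_range[2]) return(z)
  }
  NA_integer_
}

#' Simulate the ground-truth plasma proteome for a cohort
#'
#' Builds the latent quantities every downstream stage is evaluated
#' against: proteins with log-normal plasma-like abundances per patient
#' and timepoint, tryptic peptides with per-peptide ionization response
#' factors, planted baseline-differential (BD) and
#' treatment-induced-differential (TID) group effects, deglycosylated
#' sequon peptides (deamidated N in an N-X-S/T motif, X != P),
#' non-sequon deamidated decoys, and single-amino-acid variant peptides
#' restricted to carrier patients.
#'
#' BD proteins are shifted between response groups at both draws (a
#' baseline group difference that does not distort the post/baseline
#' ratio); TID proteins are shifted in the post draw of Good-responders
#' only (a treatment-response interaction).  Shift directions alternate
#' so planted effects go both ways.  BD and TID sets are disjoint.
#'
#' @param patients Patient tibble from [simulate_patients()].
#' @param n_proteins Total number of proteins.
#' @param peptides_per_protein Tryptic peptides per protein (>= 1).
#' @param n_bd,n_tid Number of planted BD / TID proteins
#'   (`n_bd + n_tid <= n_proteins`).
#' @param bd_log2_effect,tid_log2_effect Planted effect sizes as log2
#'   shifts between response groups.
#' @param n_glyco Number of sequon glycopeptides (deamidated N in
#'   N-X-S/T context).
#' @param n_deamidated_nonsequon Deamidated peptides deliberately outside
#'   a sequon, as negative cases for the glyco classifier.
#' @param n_variant Number of single-residue variant peptides.
#' @param n_variant_carriers Carrier patients per variant peptide.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   between-protein abundance distribution (arbitrary intensity units).
#' @param biological_cv Within-protein between-sample coefficient of
#'   variation (log-normal multiplicative noise).
#' @param response_factor_sdlog Log-scale SD of the per-peptide
#'   ionization response factor.
#' @param mz_range Acquisition m/z window; peptides are drawn so a charge
#'   state of 1-4 places them inside it.
#' @param seed Integer seed.
#' @return A list of class `ms_truth`: `proteins` (id, sequence, bd/tid
#'   flags and signed effects), `peptides` (sequence, modification
#'   notation, charge, theoretical m/z, reference RT, response factor,
#'   glyco/variant annotations), `abundances` (protein x patient x
#'   timepoint true abundance) and `variant_carriers`.
#' @export
simulate_ground_truth <- function(patients,
                                  n_proteins = 200, peptides_per_protein = 3,
                                  n_bd = 10, n_tid = 8,
                                  bd_log2_effect = 1.5, tid_log2_effect = 1.5,
                                  n_glyco = 10, n_deamidated_nonsequon = 5,
                                  n_variant = 5, n_variant_carriers = 3,
                                  abundance_meanlog = log(1e5),
                                  abundance_sdlog = 1,
                                  biological_cv = 0.2,
                                  response_factor_sdlog = 0.5,
                                  mz_range = c(400, 1200),
                                  seed = 1) {
  check_data_frame(patients, "patients",
                   c("patient_id", "response_group"))
  if (peptides_per_protein < 1) ms1_abort("`peptides_per_protein` must be >= 1")
  if (n_bd + n_tid > n_proteins) {
    ms1_abort("`n_bd` + `n_tid` exceeds `n_proteins`")
  }
  n_pep_total <- n_proteins * peptides_per_protein
  if (n_glyco + n_deamidated_nonsequon + n_variant > n_pep_total) {
    ms1_abort("requested special peptides exceed the total peptide count")
  }
  check_number(biological_cv, "biological_cv", lower = 0)
  check_positive(abundance_sdlog, "abundance_sdlog")
  if (n_variant > 0 && n_variant_carriers > nrow(patients)) {
    ms1_abort("`n_variant_carriers` exceeds the cohort size")
  }

  set.seed(as.integer(seed))

  # --- peptides: unique bare sequences with in-range precursors ----------
  residue_sets <- vector("list", n_pep_total)
  seen <- character(0)
  for (i in seq_len(n_pep_total)) {
    repeat {
      res <- random_tryptic_peptide()
      bare <- paste(res, collapse = "")
      z <- charge_in_range(peptide_monoisotopic_mass(notate_peptide(res)), mz_range)
      if (!bare %in% seen && !is.na(z)) {
        residue_sets[[i]] <- res
        seen <- c(seen, bare)
        break
      }
    }
  }

  protein_id <- rep(sprintf("PROT%03d", seq_len(n_proteins)),
                    each = peptides_per_protein)
  peptide_id <- sprintf("PEP%04d", seq_len(n_pep_total))

  # --- special peptide roles (disjoint) ----------------------------------
  special <- sample(n_pep_total, n_glyco + n_deamidated_nonsequon + n_variant)
  glyco_idx <- special[seq_len(n_glyco)]
  nonseq_idx <- special[n_glyco + seq_len(n_deamidated_nonsequon)]
  variant_idx <- special[n_glyco + n_deamidated_nonsequon + seq_len(n_variant)]

  deamidated_at <- vector("list", n_pep_total)
  for (i in glyco_idx) {
    res <- residue_sets[[i]]
    len <- length(res)
    pos <- sample(2:(len - 2L), 1)   # internal, room for X and S/T
    res[pos] <- "N"
    x <- sample(setdiff(PEPTIDE_ALPHABET, c("P", "C")), 1)
    res[pos + 1L] <- x
    res[pos + 2L] <- sample(c("S", "T"), 1)
    residue_sets[[i]] <- res
    deamidated_at[[i]] <- pos
  }
  for (i in nonseq_idx) {
    res <- residue_sets[[i]]
    len <- length(res)
    pos <- sample(2:(len - 2L), 1)
    res[pos] <- "N"
    res[pos + 1L] <- "P"             # X = P breaks the sequon
    residue_sets[[i]] <- res
    deamidated_at[[i]] <- pos
  }

  bare_sequence <- vapply(residue_sets, paste, character(1), collapse = "")
  modified_peptide <- vapply(seq_len(n_pep_total), function(i) {
    notate_peptide(residue_sets[[i]], deamidated_at[[i]] %||% integer(0))
  }, character(1))
  mass <- peptide_monoisotopic_mass(modified_peptide)
  charge <- vapply(mass, charge_in_range, integer(1), mz_range = mz_range)

  peptides <- tibble::tibble(
    peptide_id = peptide_id,
    protein_id = protein_id,
    bare_sequence = bare_sequence,
    modified_peptide = modified_peptide,
    charge = charge,
    theoretical_mz = precursor_mz(mass, charge),
    reference_rt = runif(n_pep_total, 5, 85),
    response_factor = rlnorm(n_pep_total, 0, response_factor_sdlog),
    is_glyco_sequon = seq_len(n_pep_total) %in% glyco_idx,
    is_deamidated = vapply(deamidated_at, function(x) length(x) > 0, logical(1)),
    is_variant = FALSE,
    variant_pos = NA_integer_,
    variant_ref = NA_character_,
    variant_alt = NA_character_,
    parent_peptide_id = NA_character_
  )

  # --- variant peptides: one substitution, carrier-restricted ------------
  variant_rows <- list()
  carriers <- list()
  for (j in seq_along(variant_idx)) {
    i <- variant_idx[j]
    res <- residue_sets[[i]]
    len <- length(res)
    pos <- sample(2:(len - 1L), 1)
    ref <- res[pos]
    alt <- sample(setdiff(PEPTIDE_ALPHABET, c(ref, "C", "P")), 1)
    vres <- res
    vres[pos] <- alt
    vbare <- paste(vres, collapse = "")
    vmass <- peptide_monoisotopic_mass(notate_peptide(vres))
    vz <- charge_in_range(vmass, mz_range)
    if (is.na(vz) || vbare %in% bare_sequence) next
    vid <- sprintf("VAR%03d", j)
    variant_rows[[length(variant_rows) + 1L]] <- tibble::tibble(
      peptide_id = vid,
      protein_id = protein_id[i],
      bare_sequence = vbare,
      modified_peptide = notate_peptide(vres),
      charge = vz,
      theoretical_mz = precursor_mz(vmass, vz),
      reference_rt = peptides$reference_rt[i] + runif(1, -2, 2),
      response_factor = peptides$response_factor[i] * runif(1, 0.3, 0.8),
      is_glyco_sequon = FALSE,
      is_deamidated = FALSE,
      is_variant = TRUE,
      variant_pos = pos,
      variant_ref = ref,
      variant_alt = alt,
      parent_peptide_id = peptides$peptide_id[i]
    )
    carriers[[length(carriers) + 1L]] <- tibble::tibble(
      peptide_id = vid,
      patient_id = sample(patients$patient_id, n_variant_carriers)
    )
  }
  if (length(variant_rows) > 0) {
    peptides <- dplyr::bind_rows(peptides, dplyr::bind_rows(variant_rows))
  }
  variant_carriers <- if (length(carriers) > 0) {
    dplyr::bind_rows(carriers)
  } else {
    tibble::tibble(peptide_id = character(0), patient_id = character(0))
  }

  # --- proteins: sequence is the concatenated tryptic backbone -----------
  backbone <- peptides[!peptides$is_variant, ]
  protein_seqs <- vapply(
    split(backbone$bare_sequence, backbone$protein_id),
    paste, character(1), collapse = ""
  )
  effect_sign <- rep_len(c(1, -1), n_proteins)
  bd_ids <- sprintf("PROT%03d", sample(n_proteins, n_bd))
  tid_pool <- setdiff(sprintf("PROT%03d", seq_len(n_proteins)), bd_ids)
  tid_ids <- sample(tid_pool, n_tid)
  proteins <- tibble::tibble(
    protein_id = sprintf("PROT%03d", seq_len(n_proteins)),
    sequence = unname(protein_seqs[sprintf("PROT%03d", seq_len(n_proteins))])
  )
  proteins$is_bd <- proteins$protein_id %in% bd_ids
  proteins$is_tid <- proteins$protein_id %in% tid_ids
  proteins$bd_log2_effect <- ifelse(proteins$is_bd,
                                    bd_log2_effect * effect_sign, 0)
  proteins$tid_log2_effect <- ifelse(proteins$is_tid,
                                     tid_log2_effect * effect_sign, 0)

  # --- true abundances per protein x patient x timepoint -----------------
  base_abundance <- rlnorm(n_proteins, abundance_meanlog, abundance_sdlog)
  noise_sdlog <- sqrt(log(1 + biological_cv^2))
  grid <- tidyr::expand_grid(
    protein_id = proteins$protein_id,
    patient_id = patients$patient_id,
    timepoint = c("baseline", "post")
  )
  grid <- dplyr::left_join(
    grid,
    dplyr::select(patients, "patient_id", "response_group"),
    by = "patient_id"
  )
  grid <- dplyr::left_join(
    grid,
    dplyr::select(proteins, "protein_id", "bd_log2_effect", "tid_log2_effect"),
    by = "protein_id"
  )
  base_lookup <- setNames(base_abundance, proteins$protein_id)
  is_good <- grid$response_group == "Good"
  log2_shift <- ifelse(is_good, grid$bd_log2_effect, 0) +
    ifelse(is_good & grid$timepoint == "post", grid$tid_log2_effect, 0)
  grid$abundance <- unname(base_lookup[grid$protein_id]) * 2^log2_shift *
    rlnorm(nrow(grid), 0, noise_sdlog)

  structure(
    list(
      proteins = proteins,
      peptides = peptides,
      abundances = dplyr::select(
        grid, "protein_id", "patient_id", "timepoint", "abundance"
      ),
      variant_carriers = variant_carriers
    ),
    class = "ms_truth"
  )
}

#' @export
print.ms_truth <- function(x, ...) {
  cat(sprintf(
    "<ms_truth> %d proteins (%d BD, %d TID), %d peptides (%d glyco-sequon, %d variant)\n",
    nrow(x$proteins), sum(x$proteins$is_bd), sum(x$proteins$is_tid),
    nrow(x$peptides), sum(x$peptides$is_glyco_sequon), sum(x$peptides$is_variant)
  ))
  invisible(x)
}
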