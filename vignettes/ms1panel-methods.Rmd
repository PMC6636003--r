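---
title: "Methods: spectral-library MS1 quantification and biomarker panel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-library MS1 quantification and biomarker panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms1panel)
```

## The analysis in one paragraph

`ms1panel` implements a label-free plasma-proteomics workflow for
predicting chemotherapy response in pancreatic cancer from paired
pre/post-treatment blood draws.  Patients are stratified by overall
survival into Good-responders (&ge; 12 months) and Limited-responders
(< 12 months).  Peptides identified by data-dependent acquisition (DDA)
in *any* run of the cohort are collected into a combined spectral
library; the precursor signal of every library peptide is then extracted
from *every* run at the MS1 level (match-between-runs), normalized to
the run's total ion current, and rolled up to proteins.  Proteins that
differ between response groups at baseline (BD) or in their
post/baseline change (TID) are discovered with two-sample t tests;
candidate BD proteins and the clinical marker CA 19-9 are combined into
a logistic biomarker panel whose score stratifies patients into
Biomarker-positive (predicted Limited-responder) and Biomarker-negative
groups, compared by Kaplan-Meier curves and the log-rank test.  Because
the underlying patient data are not publicly deposited, the package
ships a fully specified synthetic cohort generator, and every claim the
test suite makes is a property of the method, not a reproduction of
cohort-specific headline numbers.

## Quantification model

**Spectral library.**  One entry per (modified peptide, charge) observed
at identification probability &ge; 0.9 (the PeptideProphet filter level
corresponding to 1% FDR in the source workflow).  The consensus
retention time is the *median* of contributing identification RTs —
robust to occasional mis-assigned IDs; the aggregation rule is the
package's choice, as no rule is prescribed by the workflow it models.
The precursor m/z stored in the library is always computed from the
theoretical monoisotopic mass, never averaged from observations, so that
downstream mass-deviation QC measures instrument error against theory.

**Extraction.**  For each library entry and run, scans within the
retention-time window (total width `rt_window_minutes`, default 5 min,
i.e. ±2.5 min around the consensus RT) are searched.  The monoisotopic
target defines the apex scan: the most intense peak within
`ppm_tolerance` (default 3 ppm) across the window.  At that scan the
three isotope targets m/z + k·1.00335/z (k = 0, 1, 2) are matched at the
same tolerance and their intensities summed; missing isotopes contribute
zero.  Ties are resolved toward the more intense peak, then the smaller
|ppm|, then the earlier scan, making extraction deterministic on any
input.  Two readings of "a 5-min window" are possible (±5 or ±2.5); the
package centers a *total* window of 5 min and leaves the width
configurable.

**Apex summation, not peak area.**  The synthetic runs carry apex peaks
without chromatographic peak shapes, so quantification sums apex
intensities rather than integrating areas.  For real centroided data
with profile-like elution this understates abundances by a
peak-width-dependent factor; it does not affect any of the ratio-,
rank- or correlation-based statistics downstream.

**Normalization and rollup.**  IPM ("ions per million") is
`intensity / TIC × 1e6`; protein abundance is the sum of its peptides'
IPM per sample.  IPM is invariant to per-run multiplicative intensity
scaling, which is the property that makes runs comparable across
acquisition days.  Missing extractions are zeros, not NAs — extraction
always returns a number, matching the all-sample requirement of the HQ
rule below.

**HQ peptides.**  A peptide is "highly quantifiable" when it reaches
&ge; 16 IPM in every sample *and* was MS/MS-identified in every sample.

**QC.**  The ppm deviations of matched monoisotopic peaks are
summarized as mean, SD and fraction within 3 ppm.  Note that with the
default 3-ppm matching tolerance the collected deviations are truncated
at ±3 by construction, so the informative QC quantity is their SD
(which recovers the generator's 1-ppm mass-error scale), not the
within-3-ppm fraction.  Replicate-pair correlations are Pearson r on
log10(IPM + 1); the +1 offset admits zero cells, and correlations with
fewer than 3 shared features are reported absent rather than misleading.

## Differential analysis

All comparisons use the pooled-variance two-sample Student's t test at
&alpha; = 0.05 with **no multiple-testing correction by default**,
mirroring the workflow the package models (p &lt; 0.05 lists);
Benjamini-Hochberg is available via `adjust = "BH"` for users who want
FDR control.  BD proteins are tested on baseline abundances; TID
proteins on per-patient post/baseline ratios.  The ratio denominator is
floored at `ratio_epsilon` (default 0.1 IPM): `post / max(baseline, eps)`.
The floor form (rather than adding eps to the denominator) was chosen
because it leaves all nonzero ratios untouched — identical baseline and
post matrices give ratios of exactly 1 — while still guarding division
by zero.  Raw ratios are tested by default ("abundance or ratio" is the
stated basis in the modeled workflow); `log_ratio = TRUE` tests log2
ratios, which users may prefer for symmetric treatment of induction and
suppression.

Degenerate rows are handled by explicit contract: zero variance in both
groups with equal means reports t = 0, p = 1; with unequal means
`two_sample_t()` fails (the statistic is infinite).  For spectral
counts, where exact integer ties across a whole group are routine,
`variant_differential()` instead reports such rows with infinite t and
p = 0 — a carrier-restricted variant seen in every patient of one group
and never in the other is maximal evidence, not an error.

**Glycopeptide classification.**  PNGase F converts glycan-bearing
asparagine to aspartate, observed as deamidation (+0.98402 Da).  A
deamidated peptide is classified as a former N-glycopeptide when a
deamidated N sits in an N-X-S/T sequon (X &ne; P) evaluated in the full
protein sequence, so sequons completed beyond the peptide's C-terminus
are recognized.  The sequon rule itself is an inference — the modeled
workflow names only "deamidation of asparagine" — and is the standard
consensus motif.

**PCA and clustering.**  PCA (via `prcomp`) centers features and
reports explained-variance fractions over all components (summing
to 1).  Hierarchical clustering runs on log2(IPM + 1) with average or
complete linkage and euclidean or correlation distance.  Features are
canonically sorted by id before distances are computed, so the merge
tree is invariant to input row order; the leaf order is `hclust`'s
standard ordering of that canonical input, which keeps heatmaps
reproducible across sessions and platforms.

## Biomarker panel and survival

The logistic panel models the probability of *Limited* response; its
score at or above the cutoff labels a patient Biomarker-positive
(predicted Limited-responder; the boundary case is positive by
convention).  Fitting uses maximum likelihood (`glm`); when the fit
fails to converge or quasi-complete separation is detected, the panel
is refit by ridge-penalized IRLS (&lambda; = 1e-4, penalty on
non-intercept coefficients, convergence when the largest score-equation
gradient falls below 1e-8) and the training log records the
penalization.  Small cohorts with strong planted effects separate
routinely, so the fallback is part of the contract, not an edge case.

ROC curves are step curves over all distinct score thresholds with the
&ge;-threshold convention and no interpolation; the AUC is the
pair-counting (concordance) estimate with ties at 1/2, which equals the
trapezoidal area under the step curve.  Two operating points are
reported: max sensitivity at specificity &ge; 0.90 and max specificity
at sensitivity &ge; 0.90.  The cutoff maximizes specificity subject to
a sensitivity floor (default 0.90): for a predictive biomarker, missing
a patient who would benefit from treatment is the costly error.
Because the score's "sensitivity" refers to detecting
Limited-responders while the clinical argument for the 90% floor is
about not missing Good-responders, `roc_both_orientations()` reports
operating points under both readings rather than guessing one intent.
All panel evaluation is in-sample (fit and evaluated on the same
cohort), as in the modeled workflow; this overstates absolute
performance and is the main caveat on any AUC printed here.

Kaplan-Meier estimation and the log-rank test use the `survival`
package; the median is the first time S(t) &le; 0.5 and its 95% CI
comes from inverting the log-transformed Greenwood variance
(Brookmeyer-Crowley).  `loo_outlier_analysis()` re-fits the entire
panel pipeline once per held-out patient and reports each patient's
AUC shift — the package's mechanism for detecting single influential
misclassified patients, such as a Good-responder with exceptionally
high marker levels.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions everything downstream is evaluated under.

| parameter | default | rationale |
|---|---|---|
| cohort | 8 Good + 8 Limited, stage IV, 2 timepoints | proteomic discovery cohort size |
| survival (months) | truncated normal; Good 21.6 ± 7.0 on [12, &infin;), Limited 6.9 ± 3.5 on (0, 12) | clinical cohort moments; only mean ± SD are known, the truncated-normal family is the package's choice; truncation keeps labels consistent with the 12-month rule |
| draw gap | Normal(62, 12) days | clinical interval between draws |
| CA 19-9 | log-normal, stage/group-specific clinical medians, sdlog 1, baseline/post log-correlation 0.8 | spans the units-to-tens-of-thousands range seen clinically |
| censoring | none (switchable) | the modeled cohort reports none; the switch keeps survival code testable under censoring |
| proteome | 200 proteins × 3 tryptic peptides | enough for calibration studies at interactive speed |
| abundance | log-normal, sdlog 1; biological CV 20% | plasma-like dynamic range |
| planted effects | 10 BD + 8 TID proteins, |log2| = 1.5, alternating sign | well inside t-test power at n = 8/8 |
| isotope envelope | 1 : 0.5 : 0.2, spacing 1.00335/z | fixed envelope suffices to exercise 3-peak summation; a full averagine model would change nothing tested |
| mass error | Gaussian, SD 1 ppm | puts ~99.7% of monoisotopic peaks within the 3-ppm gate |
| RT jitter | SD 0.5 min on a 90-min gradient | small against the 5-min window |
| identification | per run, p = 0.7; p = 0.99 for the top 20% most intense peptides; probability values U[0.9, 1] | emulates intermittent DDA detection of low-abundance peptides while abundant peptides are identified almost every run, so an all-sample HQ set exists |
| background | 500 uniform peaks/run, log-normal intensity | low-level chemical noise; occasionally collides with a target within tolerance, as real interference does |

What the generator does **not** emulate: chromatographic peak shapes
(features are apex peaks, so area integration is untestable here),
retention-time drift requiring alignment, charge-state envelopes beyond
a single state per peptide, MS2 spectra, protein inference ambiguity
(every peptide maps to exactly one protein), and any treatment-identity
effect (regimens are not modeled).  Passing tests therefore demonstrate
the pipeline's statistical and algorithmic correctness under realistic
noise structure — not performance on real instrument data.

Variant peptides are single-residue substitutions of existing tryptic
peptides, expressed and identifiable only in their carrier patients'
runs; glycopeptide positives carry a deamidated N inside a planted
sequon, and deliberate negatives carry deamidated N followed by proline.

## Reproducibility

A single pipeline seed fans out to fixed per-stage offsets, so any
stage can be re-run in isolation and reproduce its output; the whole
pipeline is byte-reproducible for a fixed configuration, and the
manifest echoes every parameter (the output path is deliberately
excluded so runs written to different directories compare equal).
Library, matrix and cohort TSVs round-trip losslessly at 15 significant
digits.

## Problem sizes used by the test suite

The suite favors many small simulations over few large ones: oracle
equivalence on 100 random runs of ~250 peaks, null calibration over 500
cohorts of 20 proteins at n = 8/8, panel dominance over 200 cohorts at
n = 26/26, log-rank calibration over 2000 null replicates, the KM
median check as the median of 11 independent n = 500 fits (a single fit
has SE &asymp; 0.65, too noisy to pin a ±1 band), leave-one-out
influence over 100 seeded cohorts of 16 patients, and the full default
pipeline (16 patients × 2 runs, 200 proteins) executed twice for the
byte-reproducibility check.

## Known limitations

- In-sample ROC: no cross-validation by default; the optional k-fold
  variant is deliberately not wired into the default pipeline to keep
  its outputs comparable to the modeled workflow.
- No retention-time alignment: the extraction window absorbs jitter but
  not systematic drift.
- Raw-ratio TID testing is sensitive to outlying ratios; use
  `log_ratio = TRUE` when induction and suppression should weigh
  equally.
- Spectral-count comparisons use the t test on small integer counts for
  fidelity to the modeled workflow, not because it is the best count
  model.
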