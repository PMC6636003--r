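Package: ms1panel
Title: Spectral-Library MS1 Quantification and Composite Biomarker
    Evaluation for Plasma Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free plasma proteomics pipeline for chemotherapy
    response prediction: builds a cohort-combined spectral library from
    filtered peptide identifications, performs library-driven MS1
    quantification with three-isotope summation and TIC normalization
    (ions per million), discovers baseline-differential (BD) and
    treatment-induced-differential (TID) proteins, classifies
    deglycosylated N-glycopeptides and variant peptides, and evaluates
    single and composite logistic biomarker panels with ROC operating
    points, cutoff stratification and Kaplan-Meier/log-rank survival
    comparison. Includes a fully specified synthetic cohort generator
    (patients, ground-truth proteome, centroided MS1 runs,
    identifications) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
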