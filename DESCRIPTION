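Package: procad
Title: Arm-Level Copy-Number Aneuploidy Detection from Low-Coverage WGS of
    Urine Exfoliated Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Binned read-depth copy-number analysis for low-coverage whole
    genome sequencing, aimed at urine-cell based detection of prostate cancer
    chromosomal aneuploidy. Builds fixed-width bins over chromosome arms,
    normalizes per-bin coverage against a panel of benign controls, scores
    samples with bin- and arm-level Z-statistics, flags noisy libraries by the
    adjacent-bin MAD rule, segments log2 copy ratios with a from-scratch
    circular binary segmentation, and evaluates the arm-level max-|Z|
    diagnostic classifier with ROC/AUC, DeLong comparisons, Youden cutoff
    selection and Wilson continuity-corrected proportion intervals. Includes a
    negative-binomial cohort simulator with known arm-level truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
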