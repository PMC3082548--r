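Package: dyeswapr
Title: Dye-Swap Two-Colour Microarray Differential Expression with One-Class SAM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-colour spotted microarray experiments
    with a dye-swap design: per-slide Z-score low-intensity spot filtering,
    LOWESS (MA) intensity balancing with robust outlier discarding, dye-swap
    concordance filtering of replicate ratios (3 SD rule on log2(R1/R2)),
    cross-patient expression-pattern consistency filtering, geometric-mean
    ratio aggregation, one-class Significance Analysis of Microarrays (SAM)
    with sign-flip permutation FDR and 0% FDR gene calling, and
    hypergeometric gene-set over-representation. Includes a seeded synthetic
    two-channel experiment generator emulating a patient-versus-pooled-reference
    dye-swap design, and helpers for downstream validation assays (relative
    qPCR quantification by delta-Ct, exponential doubling time from two
    timepoints, MTT viability percentages, and platform concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
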