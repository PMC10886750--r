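Package: melsubtype
Title: Gene Expression Based Immune Subtyping of Melanoma Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies melanoma tumors into immune desert, excluded and
    inflamed subtypes from bulk gene expression. Implements robust
    modified z-score (median/MAD) normalization, consensus subtype
    discovery combining k-means and rule-based category scoring on an
    angiogenesis/stroma/immune gene signature, gene-wise linear models
    with empirical-Bayes moderated contrasts for marker selection, and a
    two-step seven-gene classifier (a desert vs non-desert score followed
    by an excluded vs inflamed score) with ROC/Youden cutoff optimization
    and Wilson-interval performance reporting. Includes qPCR ingestion
    with efficiency-corrected relative quantification, Kaplan-Meier and
    log-rank survival comparison, and a synthetic cohort generator that
    emulates the subtype structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC
Config/testthat/edition: 3
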