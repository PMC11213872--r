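Package: xenometab
Title: Untargeted LC-HRMS Differential Metabolomics with Biotransformation
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for untargeted liquid-chromatography
    high-resolution mass-spectrometry (LC-HRMS) differential metabolomics of
    xenobiotic-exposure cell studies. Covers feature-table quality control
    (peak-rating and QC relative-standard-deviation filters, random-forest
    missing-value imputation, QC-based signal-drift correction, median
    normalization, log transform and Pareto scaling), OPLS-DA chemometrics
    with VIP, p(corr), cross-validated Q2 and CV-ANOVA significance,
    exact-mass biotransformation-product screening from a parent compound,
    MS2 molecular networking with modified-cosine similarity, library
    annotation with MSI-style confidence levels, and a synthetic-data
    generator with ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
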