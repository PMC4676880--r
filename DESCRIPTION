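Package: mrmqc
Title: Assay Characterization and Quality Control for SRM/MRM Targeted
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes Tier 2 assay-characterization measures for
    selected/multiple reaction monitoring (SRM/MRM) assay development from
    Skyline-style transition-level peak-area exports: limit of detection,
    lower and upper limits of quantification, calibration-curve linearity,
    carry-over, intra-, inter- and total-assay coefficients of variation,
    validated LLOQ, and partial validation of specificity through
    transition-ratio stability. Measures are reported at both the
    individual-transition and summed-transition level, as tab-delimited
    reports and diagnostic figures. A seeded synthetic-data generator
    emulates response-curve and repeatability experiment designs with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
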