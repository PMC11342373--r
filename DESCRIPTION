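Package: pfasval
Title: Quantification, Confirmation and Validation Statistics for Targeted
    PFAS LC-MS/MS in Food Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for isotope-dilution, matrix-fortified
    calibration of multi-residue per- and polyfluoroalkyl substance (PFAS)
    measurements by MRM LC-MS/MS in fruit and vegetables. Implements
    internal-standard response ratios, procedural-blank correction, segmented
    1/x-weighted calibration, ion-ratio and relative-retention-time identity
    confirmation, two-branch limits of quantification and confirmation,
    apparent-recovery, repeatability and reproducibility validation statistics
    with quantitative-vs-qualitative classification, occurrence summaries with
    lower- and upper-bound sums, plus a fully seeded synthetic-batch generator
    and chromatogram simulator so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
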