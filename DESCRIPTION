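Package: densigrad
Title: Density-Gradient Deconvolution and Replication-Origin Overlap Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying naturally dense DNA from
    caesium sulphate equilibrium density gradients and relating it to DNA
    replication origins. Provides refractive-index to buoyant-density
    calibration, linear baseline correction of per-fraction DNA
    concentration profiles, least-squares deconvolution of one- or
    two-component Gaussian mixtures, dense-fraction quantification by
    trapezoidal integration, BED-style genomic interval intersection with a
    per-chromosome shuffle null, LC-MS nucleoside adduct matching for
    modified deoxycytidine composition, sequence-level modification mass
    accounting, and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
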