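Package: strainsift
Title: Metabolomics-Guided Prioritization of Antimicrobial-Producing Bacterial Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for metabolomics-guided screening of microbial extract
    libraries. Takes aligned LC-HRMS feature tables from positive and negative
    ionization modes, removes solvent-blank and culture-medium background,
    collapses adduct and isotope satellites, merges the two modes on neutral
    monoisotopic mass, predicts molecular formulas with ring-plus-double-bond
    filtering, dereplicates features against a natural-products compound
    database, fits Pareto-scaled NIPALS principal component and OPLS-DA models
    with S-plot discriminant-feature selection, buckets 1D 1H-NMR spectra for
    the same multivariate analyses, and ranks isolates by combining bioassay
    activity calls, Hotelling T-squared outlier status, dereplication novelty
    and discriminant-marker ownership. A seeded synthetic-data generator
    emulates the full input suite with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
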