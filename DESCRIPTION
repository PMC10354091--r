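Package: competeMS
Title: Competitive Chemoproteomic Target Identification from Spectral Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying covalent small-molecule targets from
    competitive chemoproteomic experiments quantified by spectral counting.
    Implements per-sample identification with competition-based exclusion
    (probe-only and inactive-analog samples anchored against no-probe and
    active-competition controls), cross-run consensus filtering, spectral-count
    prioritization and two-probe intersection, covalent-adduct calling from
    deconvoluted intact-mass peak lists, and reporter-assay activity
    normalization. Includes a negative-binomial simulator with planted specific
    targets, probe-nonspecific binders and sticky background proteins so every
    pipeline stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
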