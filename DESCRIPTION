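Package: lipidmace
Title: Comparing Lipid Parameters as Predictors of Cardiovascular Events
    After PCI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare baseline lipid parameters (LDL-C, non-HDL-C,
    atherosclerosis index, atherogenic index of plasma, lipoprotein combine
    index, LDL-C/HDL-C, apoB/apoA-I, lipoprotein(a)) as predictors of major
    adverse cardiovascular events after percutaneous coronary intervention.
    Provides cohort ingestion and validation, derived lipid indices and
    CKD-EPI eGFR, tertile exposure coding, a from-scratch Cox
    proportional-hazards fitter with Efron tie handling, the ratio of hazard
    ratios (RHR) statistic with paired percentile-bootstrap confidence
    intervals, Table-1 style descriptive comparisons, and a calibrated
    synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    nortest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
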