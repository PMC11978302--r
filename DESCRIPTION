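Package: fibromics
Title: Compartment-Specific Proteomic and Biomechanical Analysis of Liver
    Fibrosis Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for time-resolved, compartment-specific
    proteomics of liver fibrosis progression and resolution in hepatotoxic
    and cholestatic mouse models.  Implements fraction-aware label-free
    protein quantification from shared-peptide proportional coefficients,
    valid-value filtering, down-shifted Gaussian imputation of left-censored
    missing values, fold-change/t-test/Benjamini-Hochberg differential
    rules, time-course ANOVA, detergent-insoluble (ECM-enriched) fraction
    solubility profiling, hierarchical clustering with Fisher annotation
    enrichment, cell-type signature dynamics, correlation of protein
    abundance with sirius-red fibrosis area, and Hertz-model analysis of
    atomic force microscopy stiffness maps.  A synthetic-study generator
    with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
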