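Package: peptidomeDx
Title: Serum Peptidome Biomarker Discovery for Occupational Exposure
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A label-free serum peptidomics analysis pipeline for
    discriminating high from low occupational exposure to carbon
    nanotubes and nanofibers (CNT/F). Implements cross-sample ion-event
    alignment by mass, retention time and ion-mobility drift tolerances;
    reproducibility filtering, median centering, left-censored imputation
    at the limit of quantification and log2 fold standardization;
    univariate screening with Benjamini-Hochberg false discovery control;
    candidate linear-model enumeration with small-sample Akaike (AICc)
    model-selection voting; composite-exposure correlation filtering;
    partial least squares discriminant analysis (PLS-DA) with variable
    importance in projection (VIP) biomarker ranking; Monte-Carlo
    cross-validation (accuracy, R2, Q2) and unsupervised principal
    component validation. A seeded synthetic cohort and peptidome
    generator with planted exposure effects supports parameter-recovery
    testing without access to protected worker data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
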