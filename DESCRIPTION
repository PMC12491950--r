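Package: ibdmb
Title: Fecal Microbiome Analysis for IBD Inception Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Baseline fecal-microbiome analysis for inflammatory bowel disease
    (IBD) inception cohorts profiled by genus-level 16S amplicon counts.
    Provides rarefaction and alpha/beta diversity with permutation tests
    (PERMANOVA, PERMDISP), a stringent three-model consensus differential
    abundance procedure with covariate and sequencing-library random-effect
    adjustment, construction and cross-cohort transfer of a log-ratio UC-CD
    index, a composite severe-disease-course endpoint, and Monte Carlo
    cross-validated outcome prediction with additive feature attribution.
    Includes a synthetic cohort generator emulating the statistical structure
    of such studies so the full pipeline is testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    lme4,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, DifferentialExpression, Classification
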