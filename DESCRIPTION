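Package: dafit
Title: Data Augmentation for Information Transfer in Feature-Table Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for incorporating feature-stability information from small
    side studies (scan-rescan or annotate-reannotate experiments) into the
    modelling of tabular feature data such as radiomics signatures. Estimates a
    per-feature confounder noise model from paired or unpaired side studies,
    augments the main-study feature table by injecting that noise (DAFIT),
    and benchmarks the resulting models against stability-filtering and naive
    strategies with a nested cross-validation harness reporting AUC and the
    absolute estimation error against confounder-shifted test groups. Includes
    concordance-correlation and t-test stability filters, a SMOTE oversampler
    used as a sample-size control, and a synthetic benchmark generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tools,
    stats,
    utils,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
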