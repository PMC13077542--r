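Package: ieqsar
Title: Standard-Free Semi-Quantification of PFASs via QSAR-Predicted
    Ionization Efficiencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative LC-HRMS analysis of per- and
    polyfluoroalkyl substances (PFASs) that lack authentic standards.
    Calibration-curve slopes are converted into anchor-relative log10
    ionization efficiencies, a QSAR model (elastic net, random forest or
    gradient-boosted trees) maps 2D molecular descriptors to those
    efficiencies after a cleaning and recursive-feature-elimination
    cascade, and predicted efficiencies are inverted into analyte
    concentrations.  Includes fold-error evaluation utilities, a
    synthetic-data generator that emulates descriptor tables and noisy
    calibration series, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    caret,
    glmnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
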