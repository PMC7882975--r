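Package: sdmtransfer
Title: Ensemble Species Distribution Models, Transferability and Data Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Presence-background ensemble species distribution modeling with an
    AUC-weighted combination rule and median-AUC member inclusion, together with
    the experimental machinery to study how such models transfer across
    geographically distinct populations and how sensitive they are to telemetry
    sample size. Includes a virtual-species landscape simulator (autocorrelated
    covariate fields, Gaussian niche responses, GPS-like clustered sampling),
    occurrence preparation (accuracy filtering, cell deduplication, fractional
    subsampling, calibration/withheld splits, density-based background sampling),
    presence-background evaluation statistics (rank AUC over background
    proportion, continuous Boyce index, minimal predicted area), PCA-based niche
    differentiation diagnostics, declarative transferability and data-efficiency
    experiments, and dual-threshold categorical habitat mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    mgcv,
    ranger,
    xgboost,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
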