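Package: ptemarkers
Title: MR-Based Imaging Markers for Post-Traumatic Epilepsy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying imaging markers of post-traumatic
    epilepsy (PTE) in traumatic brain injury cohorts: unsupervised lesion
    scoring with a slice-wise variational autoencoder trained on
    FLAIR-like anatomy, amplitude of low-frequency fluctuation (ALFF) and
    ROI functional-connectivity features from resting-state time series,
    one-sided permutation variance F-tests with false-discovery-rate
    control, and multi-feature PTE classification with nested
    leave-one-pair-out cross-validation, permutation AUC nulls and
    learning-curve extrapolation. Includes a seeded synthetic cohort
    generator that emulates atlas-registered inputs so the entire
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    e1071,
    randomForest,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
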