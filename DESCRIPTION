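Package: salifinger
Title: Salivary Raman Fingerprint Analysis with PCA-LDA Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for surface-enhanced Raman spectra of saliva:
    polynomial baseline correction, Savitzky-Golay smoothing, reference-band
    normalization, resampling, substrate removal and artifact rejection;
    group mean and difference spectra with error propagation and peak
    attribution against a packaged saliva band catalog; and a chemometric
    classification model (PCA truncation, two-class Fisher discriminant,
    spectrum-level leave-one-out cross-validation, ROC/AUC, MCC,
    hierarchical clustering of canonical variables). Includes a synthetic
    SERS cohort generator with known ground truth so every stage can be
    exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC
Config/testthat/edition: 3
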