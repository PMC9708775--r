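Package: ramanquant
Title: Non-Invasive Quantification of HbA1c and Glucose from Skin Raman Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A chemometrics pipeline for estimating glycated hemoglobin
    (HbA1c, %) and blood glucose (mg/dL) from in vivo skin Raman spectra.
    Provides fluorescence baseline removal by genetic-algorithm fitting of
    radial polynomial expansions, Whittaker-Eilers penalized smoothing,
    self-organizing map vector quantization, RReliefF feature weighting,
    single-hidden-layer neural-network calibration trained by
    Levenberg-Marquardt or scaled conjugate gradient, comparison regressors
    (SVM, linear, interval PLS), and clinical-accuracy evaluation via
    cross-validated RMSE, the Clarke error grid, and multiclass diagnostic
    metrics. Includes a synthetic cohort generator that emulates the
    statistical structure of a 46-subject, three-site study so the whole
    pipeline can be exercised and tested without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
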