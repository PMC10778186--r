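Package: dermspectra
Title: RGB-to-Hyperspectral Reconstruction and Skin Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts calibrated RGB photographs into per-pixel visible
    reflectance spectra (380-780 nm, 1 nm) using a 24-patch color-checker
    cross-calibration between a camera and a spectrometer: tristimulus XYZ
    integration against the CIE 1931 2-degree observer, a 20-term polynomial
    correction matrix fitted by Moore-Penrose pseudoinverse, and spectral
    reconstruction on a 12-component PCA basis of the checker reflectances.
    Includes CIEDE2000 and spectral RMSE evaluation, a classical stand-in
    lesion segmenter with dice/IoU/cross-entropy metrics, spectral feature
    extraction with gradient-boosted classification under patient-grouped
    k-fold cross-validation, and synthetic-data generators (smooth
    reflectances, a parametric camera forward model, checker scenes, and
    4-class lesion image datasets) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    xgboost,
    pROC,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
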