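Package: chromaqc
Title: Chemometric Quality Control of Multicomponent Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for ultraviolet-detection liquid chromatography quality
    control of multicomponent drug products such as colistimethate sodium.
    Implements baseline estimation by an iterative mean-suppression
    (peak-filling) algorithm on a Whittaker-smoothed trace, Gaussian peak
    deconvolution with residual-driven peak addition, per-peak linear
    calibration with inverse prediction and detection/quantitation limits,
    SIMPLS partial least squares with leave-one-out cross-validation and
    jack-knife intervals, principal component analysis of peak-area ratios,
    a battery of similarity and distance measures, all-by-all peak-ratio
    matrices scored by the structural similarity index, Box-Behnken
    response-surface optimization with desirability functions, and a
    synthetic chromatogram generator with ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    proxy,
    ncdf4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
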