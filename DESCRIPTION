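Package: retpulse
Title: Objective Detection of Retinal Vessel Pulsation from Fundus Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Video photo-plethysmography for the optic disc and retina.
    Converts cardiac-gated fundus frame stacks into per-cluster pulsation
    amplitude maps via green-channel extraction, affine frame registration,
    a Beer-Lambert absorbance transform, 5x5-pixel clustering and harmonic
    regression on cardiac phase with a linear-spline movement term. Includes
    the observer-comparison framework (threshold-sweep ROC, empirical AUC,
    ideal threshold, critical amplitude, Cohen's kappa), cohort summary
    statistics with log-scale confidence intervals, and a synthetic
    pulsatile-fundus simulator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
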