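Package: holterscan
Title: Short-Window Single-Lead Holter Simulation and Diagnostic-Efficiency
    Analysis for Premature Beats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how well a short (2 hour) single-lead ambulatory
    ECG recording reproduces the premature-beat burden calls of a full 24 hour
    Holter. Provides an annotated synthetic single-lead ECG generator
    (sum-of-Gaussians beat templates, compensatory and non-compensatory
    premature beats, baseline wander and noise), a Pan-Tompkins style QRS
    detector with beat segmentation and inter-beat-interval scattergrams, a
    one-dimensional residual convolutional network beat classifier trained
    with patient-disjoint splits, frequency-based positivity calling
    (30 events per hour), and paired diagnostic-efficiency statistics:
    sensitivity, specificity, predictive values with confidence intervals,
    empirical ROC curves, and Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
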