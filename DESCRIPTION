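Package: rristress
Title: Stress Detection from RR-Interval Series with 1D Residual
    Networks and GEE Reactivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates longitudinal cohorts of beat-by-beat RR-interval
    (RRI) recordings with diagnosis-group-specific stress reactivity,
    preprocesses them into equidistant 4 Hz series via cubic-spline
    interpolation, classifies baseline versus mental-arithmetic stress
    with a modified one-dimensional ResNet34 (GELU activations,
    three-convolution residual blocks with 1x1 shortcut connections),
    evaluates classifiers with participant-level repeated k-fold
    cross-validation under separate and pooled training strategies, and
    quantifies autonomic reactivity with population-average generalized
    estimating equations (exchangeable working correlation, robust
    sandwich covariance, Wald z contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
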