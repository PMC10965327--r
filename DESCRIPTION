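Package: adtransient
Title: Predicting the End of Transient Dynamics in Anaerobic Digestion Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-free detection of the end of transient dynamics in noisy
    multivariate time series, built around a two-guild anaerobic-digestion
    chemostat. Provides the deterministic dimensional and dimensionless
    chemostat models with equilibria and a fixed-step integrator, a fast-slow
    decomposition with a staged transient approximation and its critical times,
    a stochastic analogue with multiplicative truncated-Gaussian noise for
    generating synthetic data with ground-truth transient end times, an S-map
    locally weighted linear forecaster (monitoring and control library modes),
    prediction-error curves with Gaussian trailing smoothing, threshold and
    local-maximum transient-end detectors, and an evaluation harness (identity-
    line R-squared, Pearson correlation, success proportion) with a factorial
    parameter sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
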