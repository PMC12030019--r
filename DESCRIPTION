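Package: growcast
Title: Crop Growth-Status Forecasting and Event-Triggered Irrigation Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forecasts a normalized crop growth-status signal from hourly
    greenhouse sensor streams and converts the forecast into an irrigation
    warning issued days ahead of the predicted decline. The forecaster couples
    a sparse-attention encoder-decoder (ProbSparse self-attention with
    self-attention distilling) with an LSTM refinement pass and an
    exponentially weighted moving average smoother. Includes sensor-stream
    preprocessing (Gaussian denoising, interquartile-range outlier screening,
    linear imputation, feature engineering), a three-run ensemble prediction
    protocol with decline-onset detection, closed-loop comparison of
    event-triggered against fixed weekly irrigation schedules, growth-outcome
    statistics (histogram probability densities with normal overlays, growth
    rates, plant-height comparisons), and a seeded synthetic greenhouse
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
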