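Package: nirstream
Title: Online Brain-Activation Mapping for Functional Near-Infrared
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming analysis of functional near-infrared spectroscopy
    (fNIRS) time series for block-design experiments. Raw dual-wavelength
    light intensities are converted to oxy- and deoxy-hemoglobin
    concentration changes via the modified Beer-Lambert law; a general
    linear model with a double-gamma hemodynamic response regressor,
    a baseline term and discrete-cosine high-pass drift regressors is
    then estimated sample-by-sample with a Kalman filter under a
    random-walk coefficient model, after AR(1) prewhitening of the
    serially correlated measurement noise. Running one-tailed
    t-statistics with Bonferroni correction yield a per-channel
    activation map that updates at every time step. A synthetic-data
    generator emulating task responses, physiological oscillations
    (cardiac, respiratory, Mayer wave), slow drifts and AR(1) noise
    supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
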