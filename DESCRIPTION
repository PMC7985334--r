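Package: tvcpar
Title: Time-Varying Change-Point Autoregressive Modelling of Wearable Stress Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling inertia in digitally assessed stress levels from
    wearable ecological momentary assessment (EMA) data. Implements time-varying
    change-point autoregressive (TVCP-AR) models: a penalized-spline varying-coefficient
    AR(1) captures gradual drift in intercept and autoregressive coefficient, while an
    exploratory AIC-based search with recursive binary segmentation detects abrupt regime
    shifts (change points). Includes parsing and quality control of 3-minute epoch stress
    exports with device missing codes, a piecewise AR(1) synthetic-data generator with
    realistic missingness, correlation of change-point counts with questionnaire
    outcomes (Pearson and first-order partial correlations), and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
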