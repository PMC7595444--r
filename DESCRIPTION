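Package: varcross
Title: Estimation- and Prediction-Error Crossovers Between AR(1) and VAR(1) Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for comparing first-order autoregressive
    (AR) and vector-autoregressive (VAR) models on short multivariate time
    series, as used in intensive-longitudinal (ecological momentary
    assessment) research. Samples stationary VAR(1) transition matrices from
    a multilevel population stratified on the size of autoregressive (D) and
    cross-lagged (O) effects, computes expected estimation- and
    prediction-error curves over sample size, locates the crossover sample
    sizes at which the VAR model starts to outperform the AR model, and
    compares the one-standard-error model-selection rule against picking the
    model with minimum prediction error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
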