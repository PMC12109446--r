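Package: gaitevents
Title: Gait Event Detection from Smartphone Inertial Signals with Temporal Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects heel-strike and toe-off events from thigh-mounted smartphone
    inertial recordings sampled at 50 Hz. Provides a synthetic gait signal simulator
    with exact ground-truth events, Kalman and zero-phase Butterworth preprocessing
    with low-variation channel exclusion, sliding-window dataset construction with
    age-stratified splits, three trainable sequence models (TCN-GRU, BiTCN-BiGRU and
    BiTCN-BiGRU with cross-attention) implemented natively in R, millisecond-scale
    event-timing evaluation, spatiotemporal gait parameter estimation with
    speed-adaptive stride length, and paired single-task versus dual-task comparison
    statistics with Bland-Altman agreement summaries.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
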