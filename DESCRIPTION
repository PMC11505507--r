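Package: fogcue
Title: Real-Time Freezing-of-Gait Detection and Cueing Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a wearable real-time freezing-of-gait
    (FoG) detection and cueing system for Parkinson's disease. Provides a labeled
    synthetic 40 Hz, 20-channel gait simulator (walking, standing, turning and
    trembling FoG segments), past-samples sliding-window preprocessing with an
    offline/online bit-identity guarantee, a compact single-precision CNN+RNN
    classifier trained by backpropagation through time, a streaming detector with a
    threshold function and a three-second cue countdown state machine, sample- and
    event-level evaluation (detection delay, false-positive events, sensor-group
    ablation), and the two-proportion Z-test used to quantify the effect of
    vibratory stimulation on FoG prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
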