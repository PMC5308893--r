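Package: openfieldr
Title: Open-Field Optogenetic Stimulation Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for open-field optogenetic stimulation
    experiments in rodents. Computes smoothed locomotion speed from
    centroid tracking, peri-event (pre/post stimulation) speed statistics,
    prior-speed quartile conditioning with sham-block correction for mean
    reversion, thigmotaxis and arena-zone occupancy measures, closed-loop
    region-of-interest (ROI) stimulation metrics that dissociate place
    preference from locomotor slowing, behavioral-state (ethogram)
    probabilities around stimulation, and cross-session regression of
    baseline speed on session and group. Includes a stochastic open-field
    session simulator (state-switched mean-reverting speed with persistent
    heading and wall attraction) used as ground truth throughout the test
    suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
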