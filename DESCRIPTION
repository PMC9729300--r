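Package: kickmod
Title: Reactive Agent-Based Simulation of Football Player Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A discrete-time agent-based simulator of association football
    player movement. Twenty-two purely reactive point agents perceive the
    match state (who possesses the ball), evaluate a small set of causal
    factors, and select one of seven actions per 100 ms tick, under
    attribute-driven kinematic constraints (1 m maximum step, 180 degree
    maximum turn), role-box spatial restrictions, and energy dynamics.
    Includes one-factor-at-a-time sensitivity configurations, replicate
    stabilization by coefficient of variation, and a movement/possession
    analytics toolkit: action-frequency series, dyadic relative
    orientation/distance histograms, possession matrices, and role-box
    occupancy summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
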