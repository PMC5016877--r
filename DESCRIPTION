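Package: reachkin
Title: Model-Based Kinematic Assessment of Post-Stroke Planar Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling and kinematic assessment of planar
    point-to-point reaching movements, aimed at upper-limb motor recovery
    after stroke. Tangential speed profiles are synthesized as constrained
    sums of Gaussian submovements; longitudinal and transversal components
    are coupled to the tangential peaks and integrated into workspace
    trajectories over a circular eight-target protocol. The package extracts
    the ten model-based and fourteen evaluation kinematic parameters from
    real or simulated trajectories, reconstructs shoulder and elbow angles
    with a two-link arm model, validates simulated against real curves with
    normalized trajectory-distance metrics, simulates cohorts from empirical
    parameter distributions (with a one-at-a-time sensitivity scan), and
    summarizes longitudinal parameter panels into recovery factors via
    maximum-likelihood factor analysis with promax rotation, including
    BIC-selected time-course fits of the factor scores.
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
    minpack.lm,
    pracma,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
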