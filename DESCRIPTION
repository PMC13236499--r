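Package: pendulargait
Title: Pendulum-Like Mechanical Efficiency of Walking from Motion-Capture Marker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the mechanical efficiency of human walking
    measured with optoelectronic motion capture. Detects heel-strike and
    toe-off events from foot-marker trajectories, computes the eight standard
    spatio-temporal gait parameters, estimates the body centre of mass from
    the four pelvic markers, and quantifies pendulum-like exchange between
    gravitational potential and kinetic energy through per-step positive
    works, the Energy Recovery Index and congruity. Includes Froude-based
    optimal walking speed and the Locomotor Rehabilitation Index, the
    group-level statistical battery used in clinical gait studies (paired and
    independent t tests with Cohen's d, speed-adjusted ANCOVA, Pearson
    correlations), a two-cohort synthetic gait generator for validation, and
    readers and writers for C3D and plain tabular marker files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    signal,
    car,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
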