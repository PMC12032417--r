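Package: coda24
Title: Bayesian Multilevel Compositional Data Analysis of Daily 24-Hour
    Physical Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily 24-hour physical-behavior compositions
    (sleep period, sedentary time, standing, light and moderate-to-vigorous
    physical activity) against day-level outcomes such as affective states and
    working memory, collected by ambulatory assessment. Implements Aitchison
    simplex geometry with isometric log-ratio (ilr) pivot coordinates,
    between/within-person compositional decomposition, Bayesian multilevel
    Gaussian regression with a random intercept and correlated random
    within-composition slopes (fitted by Gibbs sampling via JAGS), and
    posterior time-reallocation (substitution) analysis over 1-60 minute
    grids. A calibrated synthetic-data generator emulates the design of a
    workweek ecological momentary assessment study, enabling parameter
    recovery and calibration experiments without participant data.
License: MIT
Encoding: UTF-8
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
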