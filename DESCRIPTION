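Package: angiotraj
Title: Hierarchical Bayesian Trajectory Modelling and Nadir Alarm Rules for
    Circulating Angiogenesis Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of circulating angiogenesis
    biomarkers (Tie2, Ang1, Ca125 and companions) in randomised trials of
    VEGF-pathway inhibitors. Provides a seeded synthetic-cohort generator
    with an ICON7-style visit schedule, Pearson and partial-correlation
    biomarker networks, a hierarchical Bayesian piecewise-linear
    inflection-point model of log-concentration trajectories fitted by
    MCMC (JAGS), posterior-driven pseudo-trial simulation with monthly
    monitoring, and nadir-threshold progression-alarm rules (percent over
    nadir, GCIG-style Ca125 doubling, OR combinations) evaluated by
    prediction rate and prediction quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    rjags,
    coda,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
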