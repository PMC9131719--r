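Package: dichoptr
Title: Simulation and Analysis of Binocular Balance and Interocular
    Correlation Sensitivity Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing dichoptic psychophysics
    experiments that track short-term ocular dominance plasticity with two
    measures: the binocular phase-combination paradigm (perceived phase of
    fused gratings with equal-and-opposite 22.5 degree phase shifts) and a
    quick Bayesian adaptive estimate of the interocular correlation
    sensitivity function, modelled as a truncated log-parabola. Includes
    correlation-modulated dichoptic noise stimulus synthesis with a
    closed-form expected local interocular correlation, synthetic observer
    cohorts measured on a pre/post-deprivation session schedule under null
    or decaying-effect generative models, repeated-measures ANOVA with
    Mauchly's test and Greenhouse-Geisser correction, a BIC approximation
    to the Bayes factor in favour of the null, and exact noncentral-t
    power and minimum-sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
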