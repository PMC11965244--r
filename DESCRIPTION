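Package: fcepipe
Title: Design, Simulation, and Distributional Analysis of Flanker-Task Experiments
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete behavioral-analysis pipeline for Eriksen flanker
    experiments that manipulate target-flanker timing, mid-trial stimulus
    contrast, and stimulus location uncertainty. Builds balanced trial
    schedules (including practice blocks and block-order counterbalancing),
    simulates trial-level responses from an ex-Gaussian response-time model
    with controllable congruency effects, delta-plot slopes, error rates and
    location carry-over effects, and analyzes the resulting trial tables:
    trial classification and exclusion rules, condition summaries (mean error
    rate, median correct RT), flanker congruency effects with within-subject
    error bars, composite speed-accuracy feedback scores, De Jong delta plots
    with per-subject slope regression and Benjamini-Hochberg corrected group
    tests, repeated-measures ANOVA with Greenhouse-Geisser sphericity
    adjustment, carry-over contrasts, and a priori power computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
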