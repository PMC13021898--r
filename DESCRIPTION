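Package: rskit
Title: Simulation and Analysis of Random Soldier Kinematogram Task-Switching Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Random Soldier Kinematogram (RSK), a crowd-of-agents
    motion/color stimulus with independently parametrized motion coherence and
    uniform-color coherence. Provides a frame-by-frame stimulus simulator, exact
    generators for single-task psychometric designs and a cued task-switching
    design (sandwich structure, cue-stimulus interval manipulation with constant
    response-stimulus interval), a drift-diffusion synthetic observer that
    reproduces the qualitative behavioural regularities of the paradigm
    (psychometric monotonicity, color-task-only distractor congruence effects,
    switch costs, mixing costs, preparation benefits, asymmetric switch costs),
    and the full analysis pipeline: trial cleaning, log/arcsine transforms,
    target/distractor regressions, switch/mixing/error cost estimation,
    repeated-measures ANOVA with Greenhouse-Geisser correction, chance-level
    tests, and the switch-cost asymmetry decomposition.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
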