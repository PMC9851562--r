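Package: strooptrace
Title: Mouse-Tracking Stroop Analysis: Trajectory Kinematics, Partial
    Errors and Congruency-Effect Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for mouse-tracking colour-word Stroop
    experiments. Reads trial metadata and cursor samples, applies standard
    exclusion rules, remaps and aligns trajectories, and computes initiation
    time, response time, maximum deviation above the direct path and
    101-step time-normalized deviation and x-coordinate profiles. Detects
    partial errors by hierarchical clustering of space-normalized
    trajectories, fits linear mixed models with a colour-neutral reference
    and a parsimonious random-effect structure, estimates per-condition
    marginal means, and decomposes the Stroop congruency effect into
    interference and facilitation and their response-level and
    semantic-level subcomponents, globally and across normalized movement
    time. Includes a synthetic trajectory generator with known ground-truth
    effects so every stage can be validated offline.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
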