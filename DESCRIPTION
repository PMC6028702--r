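Package: holeboard
Title: Scoring, Simulation and Mixed-Model Analysis of Spatial Holeboard Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the spatial holeboard task, a free-choice foraging maze
    used to assess working and reference memory in pigs and other large animals.
    Converts raw hole-visit event streams into the standard per-trial behavioral
    variables (working memory, reference memory and its rotational and
    spatial-pattern components, latencies, inter-visit intervals and exploration
    counts), aggregates trials into blocks, detects learning-criterion attainment
    and reversal transitions, and fits the longitudinal linear mixed models
    (subject-in-litter random effects, first-order autoregressive residuals) used
    to compare birth-weight groups across acquisition and reversal phases.
    Includes a generative simulator of memory-guided foraging cohorts and of hair
    and salivary cortisol data for power analysis and pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
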