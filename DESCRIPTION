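Package: vplearn
Title: Simulation and Analysis of Visual Perceptual Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adaptive-staircase orientation-discrimination experiments
    and their statistical analysis: Gabor stimulus generation with task-irrelevant
    phase or contrast randomization, 3-down-1-up transformed up-down staircases
    with reversal-based threshold extraction, learning-index and transfer
    statistics (Welch tests, Pearson correlations, Fisher r-to-z comparison of
    independent correlations, Cohen's d and q, partial eta squared), aligned
    rank transform (ART) factorial analysis with subject random intercepts and
    ART-C post hoc contrasts, velocity-threshold microsaccade detection and
    fixation-variability summaries for 1000-Hz gaze traces, and a synthetic
    observer / cohort / eye-trace generator so the full pipeline is testable
    without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
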