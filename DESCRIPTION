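Package: gazemat
Title: Eyetracking Strategy Analysis for Matrix Completion Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring problem-solving strategies on matrix
    completion (Raven's-style) tasks from eyetracking data. Parses raw gaze
    samples into fixations with an adaptive per-participant velocity
    threshold, assigns fixations to areas of interest (nine matrix cells plus
    the solution array), and computes seven trial-level strategic indices
    distinguishing constructive matching from response elimination: encoding,
    integration, number of toggles, toggle rate, time to first toggle,
    proportion of time on the matrix, and the matrix time distribution index.
    Scores accuracy, relational credit and error types, derives group-wise
    item difficulty, and provides the accompanying statistical pipeline:
    outlier trimming, group comparisons, index-performance correlations,
    trial-level mixed logistic models, item-level difficulty regressions and
    per-participant random difficulty slopes (strategy-adaptation indices).
    Includes a calibrated synthetic scanpath generator so that every stage is
    testable end-to-end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
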