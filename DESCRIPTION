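Package: cwpcohort
Title: Occupational Cohort Analysis and Risk Stratification for Coal
    Workers' Pneumoconiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cumulative dust exposure for underground coal
    miners from job-spell histories and area-level concentration tables,
    estimates cumulative incidence of coal workers' pneumoconiosis (CWP)
    by the actuarial life-table method, compares incidence curves with the
    Peto log-rank test, projects the expected number of future CWP cases
    within life expectancy by occupational category, age band and future
    time window, and stratifies workers without CWP into low/middle/high
    risk classes from the predicted probabilities of a multilayer
    perceptron. A synthetic-cohort generator with known ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    yaml
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
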