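Package: flipnorms
Title: Normative Growth Curves and Scoring for the Functional Listening
    Index-Paediatric (FLI-P)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring, normative modelling and trajectory comparison for the
    Functional Listening Index-Paediatric (FLI-P), a 64-item hierarchical
    parent-report checklist of listening skills for children aged 0-72 months.
    Implements checklist scoring with basal and ceiling administration rules,
    four-parameter logistic percentile (centile) growth curves with a packaged
    reference norm table, nonlinear quantile regression by direct minimisation
    of the check (pinball) loss, a Monte Carlo sample-size procedure for
    median-curve precision, synthetic cohort generation from a percentile
    family, binned sample-percentile validation, and comparison of individual
    child trajectories against the normative envelope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
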