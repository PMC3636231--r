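Package: weightpipe
Title: Quality Control and Engagement Analysis for Self-Reported Weight
    Trajectories from Online Weight-Loss Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for retrospective cohort analyses of event-log data from
    online weight-loss programs. Screens self-reported weight entries for
    data-entry errors (digit omission, addition, transposition) with four
    automated trajectory filters plus a two-reviewer adjudication workflow
    with Cohen's kappa, constructs an analyzable cohort under a temporality
    rule linking website use to the weigh-in window, codes website-engagement
    variables as binary and per-30-day categorical predictors, and estimates
    engagement-weight-change associations via confounder screening,
    BMI-adjusted univariable models, and backward stepwise regression. A
    synthetic-data generator emulates the demographic structure, right-skewed
    usage, rapid attrition, and injected weight-entry errors of such programs
    so that filter sensitivity and effect recovery can be tested against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
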