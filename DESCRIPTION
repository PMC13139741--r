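Package: kanor
Title: Kano Model Analysis of Paired Functional-Dysfunctional Survey Items
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies survey needs with the Kano model from paired
    functional/dysfunctional five-point Likert responses: pair-level
    classification by the standard Kano evaluation table, per-item modal
    attribute assignment, better/worse satisfaction (SI) and importance (DSI)
    coefficients, and the importance-satisfaction quadrant matrix. Includes
    respondent screening (logic-error and completion-time filters), Kendall
    sample-size planning, Cronbach's alpha and Cohen's kappa reliability
    statistics, and a seeded synthetic-respondent generator with controllable
    per-item Kano structure for testing pipelines without raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
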