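Package: schoolPA
Title: Scenario Modelling of School-Based Physical Activity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population microsimulation of secondary-school physical activity
    interventions for adolescents. Generates survey-like synthetic microdata
    with a cluster design, calibrates weights to known population margins by
    iterative proportional fitting (raking), estimates five determinants of
    future physical activity with Taylor-linearised cluster-robust standard
    errors and confidence intervals, applies configurable intervention effect
    specifications with eligibility rules, ranks interventions on a scorecard,
    and costs national rollout in 2019 New Zealand dollars via consumer price
    index and purchasing power parity adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
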