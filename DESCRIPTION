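Package: cornerflow
Title: Drop-Shape Tensiometry, Contact Angles, and Biosurfactant-Induced
    Corner-Flow Prediction
Version: 0.1.0
Authors@R: person("Corner Flow", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for surfactant-driven capillary corner flows
    in angular chambers. Recovers surface tension from pendant-drop
    silhouettes by axisymmetric Young-Laplace fitting, measures advancing
    contact angles from sessile-drop images against a detected substrate
    baseline, predicts corner-flow occurrence with the Concus-Finn
    criterion, the critical corner angle, and the maximum capillary rise
    height in rounded corners, and quantifies corner-flow tip trajectories
    (onset, plateau, climbing speed) from time-lapse image stacks. Includes
    seeded synthetic generators for every input so the full chain is
    testable without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
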