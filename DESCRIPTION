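Package: edtwin
Title: Real-Time Symbiotic Simulation for Emergency Department Decision Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for short-term operational decision support in urgent and
    emergency care. Provides a synthetic real-time data feed emulating
    half-hourly departmental census snapshots, a seasonal forecaster for
    patients-in-department over a four-hour horizon, an hour-of-day crowding
    trigger estimated from historical census data, and a discrete-event
    simulation of emergency department patient flow (triage, assessment,
    investigation, treatment, clinical decision unit, downstream admission
    delay) across a network of one emergency department and three minor
    treatment centres. The components close into a symbiotic loop that updates
    every thirty minutes, initialises the simulation from mixed real-time
    conditions after a warm-up, and evaluates demand-redirection scenarios
    for low-acuity walk-in patients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
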