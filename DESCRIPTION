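Package: screenflow
Title: Stochastic Simulation of Screening Cascades and Treatment Queues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Monte-Carlo simulator of a population screening
    cascade feeding a capacity-limited treatment system. Entrants are screened
    with an instrument described by a binormal latent-score model, flow through
    referral offer and completion with probabilities stratified by true
    condition status, and join a first-in-first-out treatment queue served by a
    dynamic provider workforce with quits and lagged hiring. Supports seeded
    ensemble runs, process-level sensitivity and specificity metrics, screening
    threshold sweeps under common random numbers, hiring-lag experiments,
    waitlist feedback loops, and missed-appointment dynamics, with YAML scenario
    configuration and CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
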