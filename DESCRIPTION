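Package: stopwald
Title: Hierarchical Shifted-Wald Diffusion Modelling of Stop-Signal
    Temporal Prediction Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of go/stop
    temporal prediction (time-to-collision) experiments.  Provides the
    one-choice drift-diffusion (shifted-Wald) first-passage likelihood and
    sampler, a generative two-group cohort simulator with an independent
    horse-race stop process and a 1-up/1-down staircase on the stop-signal
    delay, race-model summaries (SSD50, mean-method SSRT, inhibition
    accuracy, context-independence checks), temporal-estimation-error
    statistics, and hierarchical fitting of competing drift-diffusion model
    variants by adaptive Metropolis-within-Gibbs sampling with DIC model
    comparison and posterior-proportion statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
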