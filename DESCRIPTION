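Package: iaif
Title: Intermittent Active Inference Agents for Continuous Pointing Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates sample-based Active Inference agents with continuous
    states, observations and actions on a one-dimensional mouse-pointing task,
    and extends them with event-triggered ("intermittent") re-planning. Agents
    sense, infer and act at every time step but start a new planning phase only
    when a Belief Divergence Trigger (symmetrised Kullback-Leibler divergence
    between the planning-time predicted belief and the current posterior) or an
    Expected Free Energy Error Trigger (the remaining plan re-scores worse than
    predicted) fires, or when the current plan is exhausted. Beliefs are
    mean-field Gaussian and propagated with an unscented Kalman filter; plans
    are scored by Monte-Carlo Expected Free Energy. Includes a Fitts-law target
    layout, perceptual noise and delay, trial and battery runners, metrics
    (time on target, planning-phase counts, hardware-independent compute
    units), and statistical comparison of agents.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
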