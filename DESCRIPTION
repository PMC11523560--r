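Package: flexfatigue
Title: Simulation-to-Reality Transfer Learning for Fatiguing Elbow Flexion Torque
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling sustained, fatiguing isometric elbow flexion.
    Includes a surrogate musculoskeletal elbow model (static optimization in
    place of computed muscle control), a three-compartment motor-unit fatigue
    model, an EMG envelope-extraction pipeline, a synthetic generator for
    recorded-style sessions (raw EMG, noisy torque, maximum voluntary
    contraction trials and a time-to-task-failure rule), and long short-term
    memory (LSTM) sequence models trained either directly on recorded-style
    data or pre-trained on simulated data and fine-tuned with frozen layers
    (transfer learning). Evaluation utilities compare both learning regimes
    against a physics-based forward-simulation baseline on leave-out subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
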