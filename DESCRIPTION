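Package: spikebayes
Title: Frequentist and Bayesian Learning for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time simulation of layered spike-response-model (SRM/LIF)
    networks together with online learning rules for them: surrogate-gradient
    frequentist training with per-layer local losses and fixed random readouts,
    straight-through-estimator training of binary synapses, and Bayesian
    mean-field variational learning with Gaussian (real-valued synapses) and
    Bernoulli (binary synapses, Gumbel-softmax relaxation) posteriors driven by
    natural-gradient updates. Includes continual-learning trainers (coreset
    replay, elastic weight consolidation, a biologically inspired
    metaplasticity rule, and Bayesian posterior-as-prior chaining), spike
    encoders for tabular features, synthetic task generators (two-moons,
    spike-template task streams), and an uncertainty-evaluation suite with
    ensemble/committee prediction, reliability diagrams, expected calibration
    error, and out-of-distribution confidence histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
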