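Package: parsyn
Title: Parallel Synapse Models of Single-Neuron Classification Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of a single neuron receiving inputs through multiple
    nonlinear parallel synapses per axon. Implements a restricted neuron with a
    fixed number of sigmoidal synaptic transmission functions per axon, trained
    by full-batch hinge-loss gradient descent with dead-synapse resurrection,
    and an unrestricted neuron whose per-axon aggregate transmission function
    is a monotone staircase fitted exactly by a convex envelope construction
    inside an importance-reweighting loop. Includes the random-pattern
    classification-capacity protocol (success-rate curves, logistic
    interpolation of the 50% crossing, nonparametric bootstrap confidence
    intervals), an exact Cover function-counting perceptron baseline with a
    linear-separability test, and a small feedforward network layer with
    monotone parallel synapses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
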