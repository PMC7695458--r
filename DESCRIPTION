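Package: rewardDDM
Title: Reward-Biased Drift-Diffusion Modelling and Neural Encoding Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reward-biased perceptual decisions and their neural
    correlates. Implements a collapsing-bound drift-diffusion model with
    reward-context-dependent drift offsets and relative bound heights, numerical
    first-passage-time solutions, maximum a posteriori fitting of choice and
    reaction-time data, and the companion single-neuron analyses: epoch and
    sliding-window spike-count regressions, a shuffle null for blocked reward
    contexts, firing-rate slope analyses linking neural modulation ratios to
    behavioural drift-rate biases, congruency tests against bound biases, and
    baseline-activity trial splitting. A synthetic-data module generates task
    behaviour and Poisson spike trains with known ground truth so every stage is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
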