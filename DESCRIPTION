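Package: pidnets
Title: Partial Information Decomposition of Small Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify redundant, unique and synergistic information
    in small artificial neural networks with partial information
    decomposition (PID). Implements the I_min and I_MMI redundancy
    functions on discrete plug-in distributions, K-order subset averaging,
    activation discretization (interquartile-range even-frequency and
    fixed-range binning), and a Gaussian-copula mutual information
    estimator for continuous activations. Ships synthetic task generators
    (logic gates, a one-dimensional delayed-reward platform environment,
    and timed two-modality decision-making trials), trainers for the small
    networks the analyses target (feedforward nets with dropout, a leaky
    ReLU recurrent network, an actor-critic policy-gradient agent), and
    experiment drivers linking synergy to lesion sensitivity, dropout,
    curricula and multitask congruence, with t-test and
    Benjamini-Hochberg summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
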