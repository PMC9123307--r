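Package: synaptoquant
Title: Quantification of Synaptic Puncta, Vesicle Pools, Field
    Potentials, Morphology, and Bayesian Group Differences
Version: 0.1.0
Authors@R:
    person("Synaptoquant", "Developers", email = "maintainer@synaptoquant.org",
           role = c("aut", "cre"))
Description: A toolkit for quantitative neuroscience assays around synaptic
    cytokine-receptor signaling: object-based two-channel colocalization of
    super-resolution synaptic puncta by iterative-threshold connected-component
    detection; readily-releasable-pool estimation from 20 Hz stimulus trains by
    back-extrapolation of cumulative EPSC amplitudes; automated miniature
    postsynaptic current detection and statistics; multitaper band power and
    amplitude-threshold spike detection in extracellular recordings; BEST-style
    Bayesian two-group estimation with an accuracy-based significance
    classification and Monte-Carlo-calibrated univariate outlier gating; Sholl
    analysis, spine classification and vesicle-distance binning. Every input
    has a matching synthetic-data generator with ground truth, so the full
    pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
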