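Package: poseSLDS
Title: Behavioral Syllable Segmentation of Animal Keypoint Trajectories
    with Switching Linear Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised segmentation of markerless pose-tracking time
    series into discrete behavioral syllables. Fits a switching linear
    dynamical system with a sticky hierarchical-Dirichlet-process
    transition prior, explicit latent centroid and heading, and a robust
    confidence-aware keypoint observation model, by Gibbs sampling.
    Includes the two-phase fitting protocol (autoregressive hidden Markov
    model initialization followed by the full model), stickiness
    calibration to a target median syllable duration, an expected
    marginal likelihood score for ranking ensembles of fits, downstream
    syllable analyses (instance extraction, cross-syllable likelihoods,
    onset-anchored trajectory summaries, ensemble transition
    probabilities), and a generative simulator with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
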