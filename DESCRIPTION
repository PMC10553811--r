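Package: probseg
Title: Probabilistic Segmentation Maps from Pairwise Same/Different Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs probabilistic visual segmentation maps (per-pixel
    probability vectors over K segments) from binary same/different judgments
    collected on pairs of image locations. Provides non-parametric estimation
    by exponentiated gradient descent under simplex constraints, with binary
    cross-entropy or squared-error objectives and optional Laplacian spatial
    regularization; parametric estimation via a multinomial logistic model over
    image features (RGB means or oriented wavelet energies), including a
    variance reparametrization for texture experiments; pair-design scheduling
    for psychophysical experiments; generators for synthetic probabilistic
    maps, simulated Bernoulli responses, and composite oriented-texture
    stimuli; and canned simulation studies with bootstrap confidence intervals
    that validate the reconstruction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
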