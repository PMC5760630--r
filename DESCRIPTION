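Package: prcnet
Title: Partial Response Coefficients for Directed Network Inference from
    Gene Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed gene networks from single-gene knockout
    expression screens using partial response coefficients (PRC), a
    maximum-likelihood covariance decomposition that is asymptotically
    unbiased with respect to additive measurement noise.  Provides the
    companion network-inferability theory for perturbation screens (the
    expected fraction of inferable links F(q) and the inferability
    measures I_F and I_F*), gene-specific noise estimation from wild-type
    replicates with a residual bootstrap for link significance, the
    subnetwork and clustering inference pipelines, synthetic knockout-screen
    generators (linear steady state and nonlinear ODE steady state), and
    inferability-aware ROC evaluation with DREAM-style scoring utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
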