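Package: scPOBDS
Title: Optimal Bayesian Classification of Single-Cell Trajectories from
    Partially-Observed Boolean Dynamical Systems
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models gene regulatory networks as partially-observed Boolean
    dynamical systems (POBDS): a Boolean network with per-gene Bernoulli
    perturbation noise observed through noisy continuous gene-expression
    measurements. Provides simulation of single-cell expression trajectories,
    exact trajectory log-likelihoods via the Boolean Kalman filter matrix
    recursion, a scalable auxiliary-particle-filter likelihood engine for
    large networks, and optimal Bayesian classification (OBC) of trajectories
    under a finite uncertainty class of candidate regulatory networks,
    together with intrinsically Bayesian robust (IBR), plug-in and
    multiple-cell baseline classifiers. Ships the 18-gene T-cell large
    granular lymphocyte (T-LGL) leukemia survival-signaling network and a
    seeded scenario runner for classification-error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
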