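Package: nbsynlik
Title: Synthetic-Model Likelihoods for Stochastic Gene Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based Bayesian inference and uncertainty
    quantification for chemical master equation (CME) models of stochastic
    gene expression. The likelihood of single-cell molecule-count data is
    approximated by a tractable surrogate ("synthetic model"): a mixture of
    negative binomials, optionally endowed with hidden-Markov dynamics over
    the observation times, fitted by expectation-maximization / Baum-Welch
    to exact stochastic simulations (Gillespie SSA, and the Extrande
    algorithm for time-varying inputs) and evaluated with the forward
    algorithm. Includes exact finite state projection (FSP) ground-truth
    likelihoods on truncated state spaces, Metropolis-Hastings posterior
    sampling with stochastic likelihood estimates, maximum-likelihood
    estimation, and three reference baselines: Gaussian synthetic
    likelihoods, moment-based inference with the linear mapping
    approximation, and sequential approximate Bayesian computation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
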