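Package: phylomcmc
Title: Bayesian Phylodynamic Inference with Time Trees, Trait Diffusion
    and Marginal Likelihood Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale statistical engine for Bayesian phylodynamics:
    Metropolis-Hastings sampling of time-scaled phylogenies under coalescent
    priors (constant size and GMRF skygrid with covariates), Felsenstein
    pruning likelihoods for nucleotide alignments and discrete traits,
    generalized-linear-model parameterization of discrete-trait
    (phylogeographic) transition rates with Bayesian stochastic search
    variable selection and Bayes factors, Markov jump and reward
    expectations with stochastic mapping, multivariate Brownian trait
    likelihoods, an adaptive multivariate transition kernel, and marginal
    likelihood estimation by path sampling, stepping-stone and generalized
    stepping-stone sampling with fitted working distributions.  Includes
    coalescent, sequence and trait simulators so every component is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
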