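# phylomcmc

Bayesian phylodynamic inference at desk scale, for people who want the
statistical core of time-tree phylodynamics — joint MCMC over time-scaled
phylogenies and evolutionary parameters — as an inspectable, fully tested
R package rather than a monolithic application.  The intended users are
molecular epidemiologists and methods developers who need to prototype,
teach, or validate phylodynamic analyses on small to medium datasets
(tens to a few hundreds of taxa).

## What it implements

* **Time trees.**  Rooted binary phylogenies with node heights (time
  before the latest tip), serial tip sampling, Newick/NEXUS/FASTA I/O,
  weighted site-pattern compression, and maximum clade credibility (MCC)
  summarization of posterior tree samples.
* **Likelihoods.**  Felsenstein pruning (compiled core, per-node
  rescaling) for HKY/GTR nucleotide models with discrete-gamma rate
  heterogeneity under a strict clock, the same engine for K-state
  discrete traits, and a linear-time multivariate Brownian likelihood
  for continuous traits.
* **Coalescent priors.**  Constant size and the GMRF skygrid: piecewise
  constant log N<sub>e</sub>(t) on a height grid with an intrinsic
  random-walk smoothing prior and optional time-varying covariates
  entering as a mean shift (w = γ − Zβ).
* **Phylogeographic GLM + BSSVS.**  Trait transition rates
  Λ<sub>ij</sub> = exp(Σ<sub>p</sub> δ<sub>p</sub> β<sub>p</sub> x<sub>ij,p</sub>)
  over standardized predictors, spike-and-slab inclusion indicators, and
  inclusion Bayes factors BF = [p/(1−p)]/[q/(1−q)].
* **Markov jumps and rewards.**  Closed-form endpoint-conditioned
  expectations of labelled transition counts and state occupancy times
  via the generator's eigensystem, plus stochastic mapping (rejection
  sampling with a uniformization fallback).
* **MCMC.**  Metropolis–Hastings over a dependency-tracked model graph:
  scale/walk/bit-flip kernels, five time-tree moves with exact Hastings
  ratios (root scale, uniform height, narrow exchange, subtree slide,
  Wilson–Balding), an adaptive multivariate normal kernel targeting
  0.234 acceptance, hierarchical priors, and ESS diagnostics.
* **Marginal likelihoods.**  Path sampling, stepping-stone, and
  generalized stepping-stone with working distributions fitted from a
  pilot posterior run.
* **Simulators.**  Coalescent trees (constant or skygrid N<sub>e</sub>,
  serial sampling), sequence alignments, discrete-trait histories with
  retained truth, Brownian traits, and predictor designs — all seeded,
  so every estimator is testable against known truth.

## Worked example

Simulate a small serially sampled outbreak and re-infer its parameters
jointly with the tree:

```r
library(phylomcmc)
set.seed(7)
tip_dates <- 2014 + runif(12, 0, 2.5)
heights   <- max(tip_dates) - tip_dates
tree_true <- simulate_coalescent_tree(heights, constant_demography(1.5),
               labels = sprintf("v%02d_%0.2f", 1:12, tip_dates))
aln <- simulate_sequences(tree_true, build_hky(c(0.3, 0.2, 0.25, 0.25), 4),
                          clock_rate = 0.004, n_sites = 1500)

g   <- seq_coalescent_graph(compress_patterns(aln), tree_true,
                            empirical_frequencies(aln),
                            kappa_init = 2, clock_init = 0.002, ne_init = 1)
fit <- run_mcmc(g, default_kernels(g), chain_length = 20000,
                log_every = 10, rng_seed = 42, store_trees = TRUE)
post <- fit$samples[-(1:500), ]   # drop burn-in
```

Posterior summaries printed by this run (truth: κ = 4, clock = 0.004,
N<sub>e</sub> = 1.5):

```
kappa        mean    5.827  95% CI [   3.502,    8.932]  ESS   394
clock_rate   mean 0.003761  95% CI [0.002748, 0.004898]  ESS    44
Ne           mean    2.274  95% CI [     1.2,    3.985]  ESS   180
root_height  mean    4.822  95% CI [   3.887,    5.926]  ESS    44
true root height: 4.403
```

Each 95% credible interval covers its true value; `ess()` reports the
autocorrelation-adjusted sample sizes, and short chains like this one
leave the clock rate the slowest-mixing quantity, as usual for
time-calibrated models.  Summarize the posterior tree sample:

```r
mcc <- mcc_tree(fit$trees, burnin_fraction = 0.25)
#> MCC root support: 1.00, log clade score -0.89
```

Node annotations `clade_support` and `mean_height` carry the posterior
clade frequencies and conditional mean heights.

A command-line front end wrapping the same functions is installed at
`inst/cli/phylomcmc` (`simulate`, `run`, `summarize`, `mltest`); every
run writes a provenance header with the config hash, seed and package
version.

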