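---
title: "Models and methods in phylomcmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phylomcmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomcmc)
```

# Scope

phylomcmc is a desk-scale Bayesian phylodynamics engine.  It jointly
samples time-scaled phylogenies and evolutionary parameters by
Metropolis–Hastings, evaluates sequence and discrete-trait likelihoods by
Felsenstein pruning, places coalescent priors (constant size or GMRF
skygrid with covariates) on the tree, parameterizes discrete-trait
(phylogeographic) transition rates as a log-linear GLM with
spike-and-slab predictor selection, computes Markov jump and reward
expectations with stochastic mapping, evaluates multivariate Brownian
trait likelihoods, and estimates marginal likelihoods by path sampling
(PS), stepping-stone (SS) and generalized stepping-stone (GSS) sampling.
Everything is validated against independent oracles (exhaustive
enumeration, uniformization series, dense multivariate-normal algebra,
direct coalescent simulation, conjugate closed forms); the simulators in
the package generate all test data, so no external datasets are needed.

Deliberate non-goals: relaxed molecular clocks (strict clock only),
codon and amino-acid models, birth–death and structured-coalescent
priors, polytomies, transmission-tree models, latent-liability and
factor models, GPU offload, and geographic visualization output.

# The time tree and its coordinate

The central sampled object is a rooted, strictly bifurcating tree whose
node *heights* measure time before the most recent sampled tip.  Heights,
not calendar dates, are the internal coordinate; dates are converted at
the I/O boundary (decimal years), either from an explicit table or from
trailing `_<year>` suffixes in taxon labels, with the explicit table
taking precedence.  Supplied dates are cross-checked against the heights
implied by branch lengths and a conflict is an error rather than a
silent reinterpretation.  All likelihoods read only height differences
(branch durations), so a strict clock rate $\mu$ converts time to
expected substitutions per site: branch "length" for the pruning
algorithm is $\mu\, r_c\, (h_{\mathrm{parent}} - h_{\mathrm{child}})$
with $r_c$ the site's discrete-gamma rate category.

# Substitution and trait models

Nucleotide models are reversible CTMCs (HKY with
transition/transversion ratio $\kappa$, or GTR), with the generator
normalized to one expected event per unit time at stationarity so that
branch lengths are identifiable in expected-event units.  Reversible
generators are diagonalized through the symmetric
$\mathrm{diag}(\sqrt\pi)\,Q\,\mathrm{diag}(1/\sqrt\pi)$ transform;
transition matrices for all branches and rate categories are assembled
from the spectral projectors inside compiled code.  Discrete-gamma rate
heterogeneity uses $k$ equal-probability categories whose rates are the
exact quantile-bin means of a Gamma$(\alpha, \alpha)$ distribution, so
the mean rate is one by construction.

Discrete-trait diffusion over $K$ states uses the same machinery with an
asymmetric generator whose off-diagonal relative rates are log-linear in
$P$ standardized predictors:
$\Lambda_{ij} = \exp\big(\sum_p \delta_p \beta_p x_{ij,p}\big)$, with
binary inclusion indicators $\delta_p$ (BSSVS).  The asymmetric form is
the default because geographic flow is directional; a reversible variant
(rates multiplied by destination frequencies) is available.  Predictors
are log-transformed where flagged and always centered and scaled to unit
variance, which makes the normal$(0, 2)$ prior on included coefficients
weakly informative.  The indicator prior is independent
Bernoulli$(q)$ with $q = 1/P$ by default, so one predictor is expected
a priori; the inclusion Bayes factor reported for predictor $p$ is the
posterior-to-prior odds ratio, with the conventional 3 / 20 / 150
support thresholds in mind.  A posterior inclusion frequency of exactly
1 over finite samples is reported as $+\infty$ with a "saturated" flag
rather than a number.

Non-reversible generators are handled by one general
eigendecomposition: the stationary distribution is read off the left
null eigenvector, and defectiveness (reconstruction error of
$VV^{-1}$ above $10^{-8}$) triggers a scaling-and-squaring matrix
exponential fallback.

# Markov jumps, rewards and stochastic mapping

Endpoint-conditioned expectations of labelled transition counts and of
time spent in designated states are evaluated in closed form through the
eigensystem: both reduce to
$\int_0^t P(s)\,B\,P(t-s)\,ds$ with $B$ carrying the labelled rates
(jumps) or a state indicator (rewards), and the scalar integrals
$(e^{\lambda_k t} - e^{\lambda_l t})/(\lambda_k - \lambda_l)$ switch to
the $t\,e^{\lambda t}$ limit when eigenvalues are within $10^{-8}$.
Defective generators fall back to a uniformization series.  Rewards over
all states sum to the branch duration, and labelled jump expectations
are additive over label partitions; both identities are enforced by
tests.  Stochastic mapping draws ancestral states from their
conditional distributions (compiled partials), then endpoint-conditioned
paths per branch by rejection sampling with a uniformization-based
fallback after 50 rejections, so termination is guaranteed even for
improbable endpoint pairs.

# Coalescent priors

The coalescent log-density sums $-\binom{k}{2}\Delta t / N_e(t)$ over
inter-event intervals and $-\log N_e$ at coalescences.  The skygrid
variant makes $\log N_e$ piecewise constant on a fixed height grid
(user-chosen cut points; the default spans the root height of the
starting tree with $M = 10$ cells) and integrates cells exactly via the
cumulative $1/N_e$ integral, which is piecewise linear in time.  The
smoothing prior is the intrinsic first-order random-walk GMRF with
precision $\tau$; its improper overall level is acceptable because the
level is identified by the coalescent likelihood.  Covariates enter as a
mean shift of the field ($w = \gamma - Z\beta_{\mathrm{cov}}$), not as
rate multipliers; epidemiological time series such as case counts are
supported only through this covariate pathway, with no separate
observation model for counts.  Suggested hyperpriors where nothing else
is known: diffuse normal$(0, 10)$ on covariate coefficients and
Gamma$(0.001, 0.001)$ on $\tau$.

# MCMC machinery

The model graph holds named parameters (scalars, vectors, indicator
vectors, a tree) with priors, and density components split into a
likelihood side and a prior side (coalescent tree prior, GMRF); only
components whose declared dependencies are touched by a proposal are
recomputed.  Kernels:

* multiplicative scale and random-walk moves for scalars and vector
  elements; bit flips for inclusion indicators;
* five time-tree moves — root-height scale, uniform internal-node
  height, narrow exchange, subtree slide, Wilson–Balding — each with
  exact Hastings ratios.  Narrow exchange picks a node with a
  grandparent and swaps it with its uncle (this formulation is
  symmetric; picking the grandparent first is not, because the
  internal/tip mix of its children can differ between states).  The
  subtree slide never proposes a topology-changing slide of the root
  edge, whose reverse move cannot be constructed; root rearrangements
  are instead reachable through narrow exchange at the root.  The
  Wilson–Balding move excludes the root edge for the same reason and
  counts eligible destination edges in both directions;
* an adaptive multivariate normal kernel over a chosen scalar set,
  proposing on transformed scales (log for positive parameters, logit
  for bounded ones, Jacobians included in the acceptance ratio).  Its
  empirical covariance is learned with diminishing $1/n$ weights
  starting after 1,000 accepted proposals (identity covariance before
  that), and the global scale follows a Robbins–Monro recursion
  ($n^{-0.6}$ steps) toward the 0.234 acceptance target.  The
  covariance is treated as fixed within each proposal, which together
  with diminishing adaptation preserves ergodicity in the standard
  adaptive-MCMC sense.

The default schedule splits weight 40% over tree moves, 40% over
single-parameter moves and 20% on the adaptive kernel; runs are
reproducible given a seed.  The decisive correctness check for the tree
moves is distributional: prior-only chains must reproduce root-height
distributions from direct coalescent simulation (contemporaneous and
serially sampled cases), which is sensitive to any Hastings error.
Hierarchical priors are available as an exchangeable normal on a
transformed scale over group members, with the group mean and precision
sampled as ordinary parameters.

Effective sample sizes use the initial-monotone-sequence truncation of
the autocorrelation sum; constant traces are flagged rather than given
a spurious ESS.

# Marginal likelihood estimation

A shared power-posterior pass samples the ladder
$1 = \beta_1 > \dots > \beta_R = 0$ (default $R = 50$, placed at
Beta$(0.3, 1)$ quantiles, which front-loads rungs near the prior where
the integrand changes fastest), each rung initialized from the previous
rung's final state.  PS applies the trapezoidal rule to per-rung mean
log-likelihoods; SS telescopes normalizing-constant ratios with
log-sum-exp stabilization.  GSS replaces the prior anchor with a
*working distribution* — independent per-parameter normals on
transformed scales, moment-matched to a pilot posterior trace with the
standard deviation inflated twofold for robustness against heavy tails —
and telescopes from it to the posterior.  Working distributions have
known normalizing constants by construction; zero-variance parameters
are treated as point masses and excluded with a warning.

Tree handling under GSS: the tree is held fixed (no tree kernels on the
GSS path), so the estimate is the scalar-parameter marginal conditional
on that tree.  This is a deliberate desk-scale simplification, recorded
in the output: it is comparable across substitution models on the same
fixed tree but not with PS/SS runs that sample trees.  The distinction
matters numerically — with the tree fixed, the coalescent density of
that tree makes the prior side unnormalized in $N_e$, so fixed-tree
PS/SS would estimate a different ratio; GSS is immune because its
reference end is explicitly normalized.  The package's validation
includes agreement of the fixed-tree GSS estimate with a direct
three-dimensional quadrature of the scalar marginal.

# The simulators, and what passing tests do and do not show

The generators produce coalescent trees under constant or skygrid
$N_e$ with serial sampling, alignments evolved site-by-site down the
tree, discrete-trait histories with the full realization retained (so
jump counts and rewards have known truth), Brownian tip traits, and
standardized random predictor designs; every output is seeded and truth
parameters are written alongside the data.

The standing study conditions used by the validation suite were chosen
once as typical of a small, densely sampled viral outbreak and then
frozen: 20 taxa sampled uniformly over 3 years, 1,000 sites, HKY with
$\kappa = 4$ and empirical-style frequencies $(0.30, 0.20, 0.25,
0.25)$, clock $5\times 10^{-3}$ substitutions/site/year, $N_e = 2$
years for the sequence-recovery checks; a fixed 50-tip contemporaneous
tree with $K = 6$ locations, two predictors (one with true effect
$\beta = 1$, one null) and a trait clock of 3 expected events per unit
time for the phylogeographic GLM checks.  Chain lengths (25,000 steps
for sequence recovery, 20,000 for the trait GLM, with the first fifth
to quarter discarded) were set for adequate mixing at these sizes.

Synthetic data of this kind exercises the estimators under their own
assumptions.  It does not probe model misspecification (rate variation
beyond discrete-gamma, non-clocklike evolution, sampling biased by
location, recombination), alignment error, or the scale of real
surveillance datasets with thousands of genomes and dozens of demes.
Passing the suite therefore demonstrates correctness of the
implemented models and samplers, not robustness of those models to
real-data violations.

# Numerical choices and degenerate inputs

* Pruning partials are rescaled per node and pattern when the largest
  partial drops below $10^{-40}$, with log factors accumulated, so
  likelihoods never underflow to `NaN`.
* Transition-probability rows are clipped at zero and renormalized to
  absorb eigendecomposition roundoff.
* Postorder orderings are obtained by sorting internal nodes on height,
  valid because heights strictly increase child to parent.
* Site patterns are compressed with exact weights; compression is
  verified never to change a likelihood.
* MCC clade identity uses exact sorted-tip-index keys over a fixed
  taxon ordering (the practical equivalent of a bitset, chosen for
  simplicity in R); selection is verified against brute-force scoring.
* Zero-length branches contribute no stochastic-mapping events; a
  branch of length zero with unequal endpoints is an error.
* The burn-in fraction for MCC summarization is a required argument:
  no default is claimed because none would fit all chain lengths.

# Known limitations

Pure-R tree moves cap practical problem sizes at hundreds of tips;
likelihood evaluation (compiled) is not the bottleneck, bookkeeping is.
The adaptive kernel covers scalar parameters only.  GSS over jointly
sampled trees is out of scope, as are checkpointing beyond seed plus
final state and parallel chains.  The fixed-tree GSS caveat above
applies whenever its output is compared across analyses.
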