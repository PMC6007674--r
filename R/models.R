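## ------------------------------------------------------------------
## Ready-made model graphs for the standard analyses, wiring the
## likelihood modules into the MCMC engine, plus the default kernel
## schedule (tree moves 40%, single-parameter moves 40%, adaptive
## multivariate kernel 20%).
## ------------------------------------------------------------------

lognormal_prior <- function(meanlog, sdlog)
  function(value, state) dlnorm(value, meanlog, sdlog, log = TRUE)

normal_prior <- function(mean, sd)
  function(value, state) dnorm(value, mean, sd, log = TRUE)

gamma_prior <- function(shape, rate)
  function(value, state) dgamma(value, shape, rate = rate, log = TRUE)

bernoulli_prior <- function(q)
  function(value, state) sum(value * log(q) + (1 - value) * log(1 - q))

#' Joint sequence + coalescent model graph
#'
#' HKY substitution model with fixed (empirical) base frequencies, a
#' strict clock, and a constant-size coalescent tree prior.  Sampled
#' parameters: `kappa`, `clock_rate`, `Ne` and the time tree.
#'
#' @param patterns a `patternset` from [compress_patterns()].
#' @param tree_init starting `timetree`.
#' @param freqs base frequencies (e.g. empirical from the alignment).
#' @param site_rates a `site_rate_model`.
#' @param kappa_init,clock_init,ne_init initial values.
#' @param kappa_prior,clock_prior,ne_prior prior functions
#'   `(value, state) -> log density`; defaults are diffuse lognormals.
#' @return a `model_graph`.
#' @export
seq_coalescent_graph <- function(patterns, tree_init, freqs,
                                 site_rates = uniform_rate_model(),
                                 kappa_init = 2, clock_init = 0.01,
                                 ne_init = 1,
                                 kappa_prior = lognormal_prior(1, 1.25),
                                 clock_prior = lognormal_prior(0, 3),
                                 ne_prior = lognormal_prior(0, 2)) {
  pm0 <- partition_model(patterns, build_hky(freqs, kappa_init),
                         site_rates = site_rates, clock_rate = 1)
  hky_cache <- new.env(parent = emptyenv())
  hky_for <- function(kappa) {
    if (!identical(hky_cache$kappa, kappa)) {
      hky_cache$kappa <- kappa
      hky_cache$model <- build_hky(freqs, kappa)
    }
    hky_cache$model
  }
  seq_lik <- function(state) {
    prune_loglik(state$tree, pm0, model = hky_for(state$kappa),
                 clock_rate = state$clock_rate)
  }
  coal_prior <- function(state)
    coalescent_loglik(state$tree, constant_demography(state$Ne))
  model_graph(
    params = list(
      param_spec("kappa", kappa_init, kappa_prior, "log"),
      param_spec("clock_rate", clock_init, clock_prior, "log"),
      param_spec("Ne", ne_init, ne_prior, "log"),
      param_spec("tree", tree_init, NULL, "none", type = "tree")
    ),
    components = list(
      density_component("seq_lik", seq_lik,
                        depends = c("kappa", "clock_rate", "tree")),
      density_component("coalescent", coal_prior,
                        depends = c("Ne", "tree"), role = "prior")
    ))
}

#' Empirical base frequencies of an alignment
#' @param aln character matrix alignment.
#' @return length-4 frequency vector (A, C, G, T), ambiguities ignored.
#' @export
empirical_frequencies <- function(aln) {
  tab <- table(factor(toupper(as.vector(aln)), levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab)
  if (any(f == 0)) f <- f + 1  # guard degenerate alignments
  f / sum(f)
}

#' Discrete-trait GLM diffusion model graph on a fixed tree
#'
#' Sampled parameters: GLM coefficients `beta` (spike-and-slab normal
#' priors), inclusion indicators `delta` (independent Bernoulli with
#' prior expected count 1, i.e. q = 1/P, unless overridden) and the
#' trait clock rate.  The tree is held fixed.
#'
#' @param tree fixed `timetree`.
#' @param design standardized `K(K-1) x P` predictor matrix.
#' @param tip_states named character vector taxon -> state label.
#' @param levels the K state labels.
#' @param q prior inclusion probability (default `1/P`).
#' @param beta_sd prior standard deviation of included coefficients.
#' @param clock_init initial trait clock rate.
#' @param clock_prior prior on the trait clock rate.
#' @param reversible use the reversible GLM variant.
#' @return a `model_graph`.
#' @export
trait_glm_graph <- function(tree, design, tip_states, levels,
                            q = 1 / ncol(design), beta_sd = 2,
                            clock_init = 1,
                            clock_prior = lognormal_prior(0, 1.5),
                            reversible = FALSE) {
  P <- ncol(design)
  K <- length(levels)
  tp <- trait_tip_partials(tip_states[tree$tip_label], levels)
  pats <- list(patterns = NULL, weights = 1, taxa = tree$tip_label)
  freqs <- if (reversible) rep(1 / K, K) else NULL
  pm0 <- partition_model(pats, glm_rate_matrix(design, rep(0, P), rep(0, P),
                                               K, freqs = freqs,
                                               reversible = reversible),
                         clock_rate = clock_init, tip_partials = tp)
  trait_lik <- function(state) {
    m <- glm_rate_matrix(design, state$beta, state$delta, K, freqs = freqs,
                         reversible = reversible)
    prune_loglik(tree, pm0, model = m, clock_rate = state$trait_clock)
  }
  model_graph(
    params = list(
      param_spec("beta", rep(0, P), normal_prior(0, beta_sd), "none",
                 type = "vector"),
      param_spec("delta", rep(1, P), bernoulli_prior(q), "none",
                 type = "indicator"),
      param_spec("trait_clock", clock_init, clock_prior, "log")
    ),
    components = list(
      density_component("trait_lik", trait_lik,
                        depends = c("beta", "delta", "trait_clock"))
    ))
}

#' Conjugate normal-mean toy model
#'
#' i.i.d. observations `y ~ N(mu, sigma^2)` with known `sigma` and a
#' `N(mu0, tau0^2)` prior on `mu`; its marginal likelihood is available
#' in closed form, making it the standard validation battery for the
#' marginal-likelihood estimators.
#'
#' @param y observations.
#' @param sigma known observation standard deviation.
#' @param mu0,tau0 prior mean and standard deviation.
#' @return a `model_graph` with the single parameter `mu`.
#' @export
normal_mean_graph <- function(y, sigma = 1, mu0 = 0, tau0 = 1) {
  model_graph(
    params = list(param_spec("mu", mean(y), normal_prior(mu0, tau0), "none")),
    components = list(
      density_component("obs", function(state)
        sum(dnorm(y, state$mu, sigma, log = TRUE)), depends = "mu")
    ))
}

#' Default kernel schedule for a model graph
#'
#' Tree moves carry 40% of the total weight (split over the five move
#' kinds), single-parameter scale/walk/bit-flip moves 40%, and the
#' adaptive multivariate kernel 20% (when at least two scalar
#' parameters exist).
#'
#' @param graph a `model_graph`.
#' @param tree_name tree parameter name, if present.
#' @param slide_sd subtree-slide tuning (tree-height scale units).
#' @param start_adapt acceptances before covariance learning.
#' @return list of kernels for [run_mcmc()].
#' @export
default_kernels <- function(graph, tree_name = "tree", slide_sd = 0.5,
                            start_adapt = 1000) {
  params <- graph$params
  has_tree <- !is.null(params[[tree_name]]) &&
    params[[tree_name]]$type == "tree"
  scalars <- names(params)[vapply(params, function(p) p$type == "scalar", TRUE)]
  vectors <- names(params)[vapply(params, function(p) p$type == "vector", TRUE)]
  indicators <- names(params)[vapply(params, function(p)
    p$type == "indicator", TRUE)]
  kernels <- list()
  n_single <- length(scalars) + length(vectors) + length(indicators)
  w_single <- 0.4 / max(n_single, 1)
  for (nm in scalars) {
    tr <- params[[nm]]$transform
    kernels[[length(kernels) + 1L]] <-
      if (tr == "log") kernel_scale(nm, weight = w_single)
      else kernel_walk(nm, weight = w_single)
  }
  for (nm in vectors)
    kernels[[length(kernels) + 1L]] <- kernel_walk(nm, weight = w_single)
  for (nm in indicators)
    kernels[[length(kernels) + 1L]] <- kernel_bitflip(nm, weight = w_single)
  if (length(scalars) >= 2L)
    kernels[[length(kernels) + 1L]] <-
      kernel_adaptive_mvn(scalars, graph, weight = 0.2,
                          start_adapt = start_adapt)
  if (has_tree) {
    kinds <- c("root_scale", "uniform_height", "narrow_exchange",
               "subtree_slide", "wilson_balding")
    for (k in kinds)
      kernels[[length(kernels) + 1L]] <-
        kernel_tree(k, tree_name = tree_name, weight = 0.4 / length(kinds),
                    tuning = if (k == "subtree_slide") slide_sd else 0.5)
  }
  kernels
}
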