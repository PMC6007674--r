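## ------------------------------------------------------------------
## Marginal likelihood estimation: power-posterior sampling shared by
## path sampling (PS) and stepping-stone (SS), and the generalized
## stepping-stone (GSS) path from a fitted working distribution (a
## product of per-parameter normals on transformed scales, with known
## normalizing constant) to the posterior.
## ------------------------------------------------------------------

#' Inverse-temperature ladder at Beta-distribution quantiles
#'
#' `R` rungs `1 = beta_1 > ... > beta_R = 0`, placed at evenly spaced
#' quantiles of a Beta(shape, 1) distribution; `shape < 1` concentrates
#' rungs near the prior where the integrand changes fastest.
#'
#' @param R number of rungs (>= 2).
#' @param shape Beta first parameter (default 0.3, established
#'   stepping-stone practice).
#' @return decreasing numeric vector of length `R`.
#' @export
beta_ladder <- function(R, shape = 0.3) {
  stopifnot(R >= 2)
  (seq(R - 1, 0) / (R - 1))^(1 / shape)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Sample a power-posterior ladder
#'
#' For each rung the MCMC targets `prior * likelihood^beta` (PS/SS) or,
#' when a reference is supplied, `(prior * likelihood)^beta *
#' reference^(1-beta)` (GSS).  Rungs run from the posterior down,
#' each initialized from the previous rung's final state (sequential
#' annealing).
#'
#' @param graph a [model_graph()].
#' @param kernels kernel list for [run_mcmc()].
#' @param betas decreasing inverse temperatures (e.g. [beta_ladder()]).
#' @param n_samples retained samples per rung.
#' @param burnin discarded iterations per rung.
#' @param log_every thinning interval.
#' @param rng_seed seed.
#' @param reference optional working distribution (see
#'   [fit_working_distribution()]) switching the path to GSS.
#' @return a `power_posterior_ladder`: list with `betas`, `loglik`
#'   (samples x rungs), and for GSS `logratio` (log posterior-density
#'   minus log reference-density samples).
#' @export
run_power_posterior <- function(graph, kernels, betas, n_samples = 500,
                                burnin = 200, log_every = 1, rng_seed = NULL,
                                reference = NULL) {
  stopifnot(all(diff(betas) < 0), abs(betas[1] - 1) < 1e-12)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  R <- length(betas)
  niter <- burnin + n_samples * log_every
  ll <- matrix(NA_real_, n_samples, R)
  lr <- if (!is.null(reference)) matrix(NA_real_, n_samples, R)
  ref_fn <- if (!is.null(reference))
    function(state) working_log_density(reference, state)
  state <- NULL
  for (r in seq_len(R)) {
    tr <- run_mcmc(graph, kernels, niter, log_every = log_every,
                   init_state = state, power = betas[r],
                   reference = ref_fn)
    keep <- tail(seq_len(nrow(tr$samples)), n_samples)
    ll[, r] <- tr$samples$likelihood[keep]
    if (!is.null(reference)) {
      smp <- tr$samples[keep, , drop = FALSE]
      refv <- working_log_density_trace(reference, smp)
      lr[, r] <- smp$prior + smp$likelihood - refv
    }
    state <- tr$final_state
  }
  structure(list(betas = betas, loglik = ll, logratio = lr,
                 kind = if (is.null(reference)) "power" else "gss"),
            class = "power_posterior_ladder")
}

#' Path-sampling estimate of the log marginal likelihood
#'
#' Trapezoidal rule over the inverse temperature of the per-rung mean
#' log-likelihood.
#'
#' @param ladder a `power_posterior_ladder` (PS/SS kind).
#' @return log marginal likelihood.
#' @export
path_sampling_estimate <- function(ladder) {
  b <- ladder$betas
  if (length(b) < 2) stop("need at least 2 rungs")
  m <- colMeans(ladder$loglik)
  sum((b[-length(b)] - b[-1]) * (m[-length(m)] + m[-1]) / 2)
}

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Telescoped ratios of normalizing constants between adjacent rungs,
#' each estimated from the colder rung's samples with log-sum-exp
#' stabilization.
#'
#' @param ladder a `power_posterior_ladder`.
#' @return log marginal likelihood.
#' @export
stepping_stone_estimate <- function(ladder) {
  b <- ladder$betas
  if (length(b) < 2) stop("need at least 2 rungs")
  x <- if (ladder$kind == "gss") ladder$logratio else ladder$loglik
  s <- 0
  for (r in seq_len(length(b) - 1L))
    s <- s + logmeanexp((b[r] - b[r + 1]) * x[, r + 1L])
  s
}

## -- working distributions -----------------------------------------

#' Fit a working distribution from a posterior trace
#'
#' Independent normal densities on each scalar parameter's transformed
#' scale, moment-matched to the posterior samples with the standard
#' deviation inflated for robustness (heavy-tailed posteriors keep
#' finite importance ratios).  Zero-variance parameters are treated as
#' fixed point masses and excluded, with a warning.
#'
#' @param trace an `mcmc_trace` from a posterior run.
#' @param graph the model graph (for parameter transforms).
#' @param params scalar parameter names (default: all non-tree scalars).
#' @param inflate standard-deviation inflation factor (default 2).
#' @param min_ess warn when a parameter's trace ESS falls below this.
#' @return a `working_distribution`.
#' @export
fit_working_distribution <- function(trace, graph, params = NULL,
                                     inflate = 2, min_ess = 100) {
  if (is.null(params))
    params <- names(graph$params)[vapply(graph$params, function(p)
      p$type == "scalar", TRUE)]
  trs <- vapply(graph$params[params], `[[`, "", "transform")
  mu <- sdv <- setNames(numeric(length(params)), params)
  keep <- logical(length(params))
  for (i in seq_along(params)) {
    x <- trace$samples[[params[i]]]
    if (is.null(x)) stop("parameter ", params[i], " not in trace")
    y <- transform_fwd(x, trs[i])
    if (var(y) == 0) {
      warning("zero-variance parameter ", params[i],
              " treated as a fixed point mass")
      next
    }
    if (ess(y) < min_ess)
      warning("low ESS (", round(ess(y)), ") for parameter ", params[i])
    mu[i] <- mean(y)
    sdv[i] <- sd(y) * inflate
    keep[i] <- TRUE
  }
  structure(list(params = params[keep], transforms = trs[keep],
                 mean = mu[keep], sd = sdv[keep], inflate = inflate),
            class = "working_distribution")
}

#' Log density of a working distribution at a state
#' @param wd a `working_distribution`.
#' @param state named state list.
#' @return log density (on the original parameter scale).
#' @export
working_log_density <- function(wd, state) {
  s <- 0
  for (i in seq_along(wd$params)) {
    x <- state[[wd$params[i]]]
    y <- transform_fwd(x, wd$transforms[i])
    s <- s + dnorm(y, wd$mean[i], wd$sd[i], log = TRUE) -
      transform_logjac(x, wd$transforms[i])
  }
  s
}

working_log_density_trace <- function(wd, samples) {
  s <- numeric(nrow(samples))
  for (i in seq_along(wd$params)) {
    x <- samples[[wd$params[i]]]
    y <- transform_fwd(x, wd$transforms[i])
    s <- s + dnorm(y, wd$mean[i], wd$sd[i], log = TRUE) -
      transform_logjac(x, wd$transforms[i])
  }
  s
}

#' Generalized stepping-stone estimate
#'
#' Runs the GSS path from the working distribution (known normalizing
#' constant) to the posterior and applies the stepping-stone identity
#' to the per-sample log posterior-minus-reference ratios.  Tree
#' parameters, if any, are kept fixed at their current value throughout
#' (the working distribution covers scalar parameters only).
#'
#' @inheritParams run_power_posterior
#' @param working a fitted [fit_working_distribution()].
#' @return list with `logml` and the `ladder`.
#' @export
gss_estimate <- function(graph, kernels, working, betas, n_samples = 500,
                         burnin = 200, log_every = 1, rng_seed = NULL) {
  ladder <- run_power_posterior(graph, kernels, betas,
                                n_samples = n_samples, burnin = burnin,
                                log_every = log_every, rng_seed = rng_seed,
                                reference = working)
  list(logml = stepping_stone_estimate(ladder), ladder = ladder)
}
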