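## ------------------------------------------------------------------
## Metropolis-Hastings engine over a joint model graph: named parameter
## nodes with priors (scalars, vectors, inclusion indicators, a time
## tree), density components split into prior-side (coalescent, GMRF)
## and likelihood-side (partitions, traits) so that power posteriors
## raise only the likelihood side to beta.
## ------------------------------------------------------------------

#' Declare a sampled parameter
#'
#' @param name parameter name (key in the state list).
#' @param init initial value.
#' @param log_prior function `(value, state) -> log density`; may read
#'   other parameters from `state` (hierarchical priors).  `NULL` for
#'   tree parameters, whose prior is a density component.
#' @param transform scale used by the adaptive multivariate kernel:
#'   `"log"` for positive parameters, `"logit"` for (0,1), `"none"`.
#' @param type `"scalar"`, `"vector"`, `"indicator"` or `"tree"`.
#' @return a parameter spec.
#' @export
param_spec <- function(name, init, log_prior = NULL,
                       transform = c("none", "log", "logit"),
                       type = c("scalar", "vector", "indicator", "tree")) {
  list(name = name, init = init, log_prior = log_prior,
       transform = match.arg(transform), type = match.arg(type))
}

#' Declare a density component
#'
#' @param name component name.
#' @param fn function `(state) -> log density`.
#' @param depends names of parameters the component reads; only
#'   components touched by a proposal are recomputed.
#' @param role `"likelihood"` components are raised to the inverse
#'   temperature in power-posterior runs; `"prior"` components
#'   (coalescent tree prior, GMRF field prior) are not.
#' @return a component spec.
#' @export
density_component <- function(name, fn, depends,
                              role = c("likelihood", "prior")) {
  list(name = name, fn = fn, depends = depends, role = match.arg(role))
}

#' Assemble a model graph
#'
#' @param params list of [param_spec()]s.
#' @param components list of [density_component()]s.
#' @return a `model_graph`.
#' @export
model_graph <- function(params, components = list()) {
  names(params) <- vapply(params, `[[`, "", "name")
  names(components) <- vapply(components, `[[`, "", "name")
  structure(list(params = params, components = components),
            class = "model_graph")
}

graph_init_state <- function(graph) {
  lapply(graph$params, `[[`, "init")
}

param_log_prior <- function(graph, state) {
  s <- 0
  for (p in graph$params) {
    if (is.null(p$log_prior)) next
    s <- s + sum(p$log_prior(state[[p$name]], state))
  }
  s
}

eval_components <- function(graph, state, which = names(graph$components)) {
  vapply(graph$components[which], function(cmp) cmp$fn(state), numeric(1))
}

## -- scalar/vector kernels -----------------------------------------

#' Multiplicative scale kernel for a positive scalar
#' @param name target parameter.
#' @param delta log-scale window.
#' @param weight sampling weight in the kernel schedule.
#' @return a kernel.
#' @export
kernel_scale <- function(name, delta = 0.7, weight = 1) {
  list(kind = "scale", name = paste0("scale(", name, ")"), weight = weight,
       touched = name,
       propose = function(state) {
         f <- exp(delta * (runif(1) - 0.5))
         state[[name]] <- state[[name]] * f
         list(state = state, loghr = log(f))
       })
}

#' Random-walk kernel (one random element for vectors)
#' @param name target parameter.
#' @param sd proposal standard deviation.
#' @param weight schedule weight.
#' @return a kernel.
#' @export
kernel_walk <- function(name, sd = 0.5, weight = 1) {
  list(kind = "walk", name = paste0("walk(", name, ")"), weight = weight,
       touched = name,
       propose = function(state) {
         x <- state[[name]]
         i <- if (length(x) > 1L) sample.int(length(x), 1L) else 1L
         x[i] <- x[i] + rnorm(1, 0, sd)
         state[[name]] <- x
         list(state = state, loghr = 0)
       })
}

#' Indicator bit-flip kernel for BSSVS inclusion vectors
#' @param name target indicator parameter.
#' @param weight schedule weight.
#' @return a kernel.
#' @export
kernel_bitflip <- function(name, weight = 1) {
  list(kind = "bitflip", name = paste0("bitflip(", name, ")"),
       weight = weight, touched = name,
       propose = function(state) {
         x <- state[[name]]
         i <- sample.int(length(x), 1L)
         x[i] <- 1 - x[i]
         state[[name]] <- x
         list(state = state, loghr = 0)
       })
}

transform_fwd <- function(x, tr) switch(tr, none = x, log = log(x),
                                        logit = log(x / (1 - x)))
transform_bwd <- function(y, tr) switch(tr, none = y, log = exp(y),
                                        logit = 1 / (1 + exp(-y)))
## log |dx/dy|: Jacobian of the back-transform, entering the ratio
transform_logjac <- function(x, tr) switch(tr, none = 0, log = log(x),
                                           logit = log(x) + log(1 - x))

#' Adaptive multivariate normal kernel
#'
#' Jointly updates a set of scalar parameters on transformed scales:
#' `x' = x + s L z` with `L = chol(Sigma_emp + eps I)`.  The global
#' scale `s` is tuned toward an acceptance rate of 0.234 and the
#' empirical covariance is learned with diminishing (1/n) weights;
#' until `start_adapt` acceptances have accrued the proposal uses the
#' identity covariance (cold start).
#'
#' @param names scalar parameters to update jointly (>= 2).
#' @param graph the model graph (for the transforms).
#' @param weight schedule weight.
#' @param start_adapt acceptances before covariance learning begins.
#' @param s0 initial global scale.
#' @param eps ridge added to the empirical covariance.
#' @return a kernel (stateful: adaptation lives in its environment).
#' @export
kernel_adaptive_mvn <- function(names, graph, weight = 1,
                                start_adapt = 1000, s0 = 0.4, eps = 1e-6) {
  if (length(names) < 2L) stop("adaptive kernel needs >= 2 parameters")
  trs <- vapply(graph$params[names], `[[`, "", "transform")
  d <- length(names)
  env <- new.env()
  env$n <- 0L; env$naccept <- 0L
  env$mean <- rep(0, d)
  env$cov <- diag(d)
  env$logs <- log(s0 / sqrt(d))
  env$nadapt <- 0L
  propose <- function(state) {
    x <- vapply(names, function(nm) state[[nm]], numeric(1))
    y <- mapply(transform_fwd, x, trs)
    s <- exp(env$logs)
    Lc <- if (env$naccept >= start_adapt) {
      chol(env$cov + eps * diag(d))
    } else diag(d)
    ynew <- y + s * as.vector(t(Lc) %*% rnorm(d))
    xnew <- mapply(transform_bwd, ynew, trs)
    loghr <- sum(mapply(transform_logjac, xnew, trs)) -
      sum(mapply(transform_logjac, x, trs))
    for (i in seq_len(d)) state[[names[i]]] <- xnew[i]
    list(state = state, loghr = loghr, y = y)
  }
  notify <- function(accepted, alpha, y) {
    env$n <- env$n + 1L
    if (accepted) env$naccept <- env$naccept + 1L
    ## running moments of the (pre-proposal) transformed state
    env$nadapt <- env$nadapt + 1L
    g <- 1 / env$nadapt
    dlt <- y - env$mean
    env$mean <- env$mean + g * dlt
    env$cov <- env$cov + g * (outer(dlt, y - env$mean) - env$cov)
    env$cov <- (env$cov + t(env$cov)) / 2
    ## Robbins-Monro scale adaptation toward 0.234
    env$logs <- env$logs + env$nadapt^-0.6 * (alpha - 0.234)
  }
  list(kind = "adaptive_mvn", name = "adaptive_mvn", weight = weight,
       touched = names, propose = propose, notify = notify, env = env)
}

#' Tree move kernel
#' @param kind one of `"root_scale"`, `"uniform_height"`,
#'   `"narrow_exchange"`, `"subtree_slide"`, `"wilson_balding"`.
#' @param tree_name name of the tree parameter.
#' @param weight schedule weight.
#' @param tuning move-specific tuning (scale window / slide sd).
#' @return a kernel.
#' @export
kernel_tree <- function(kind = c("root_scale", "uniform_height",
                                 "narrow_exchange", "subtree_slide",
                                 "wilson_balding"),
                        tree_name = "tree", weight = 1, tuning = 0.5) {
  kind <- match.arg(kind)
  mover <- switch(kind,
    root_scale = function(tr) move_root_scale(tr, tuning),
    uniform_height = move_uniform_height,
    narrow_exchange = move_narrow_exchange,
    subtree_slide = function(tr) move_subtree_slide(tr, tuning),
    wilson_balding = move_wilson_balding)
  list(kind = paste0("tree_", kind), name = paste0("tree_", kind),
       weight = weight, touched = tree_name,
       propose = function(state) {
         prop <- mover(state[[tree_name]])
         if (is.null(prop)) return(NULL)
         state[[tree_name]] <- prop$tree
         list(state = state, loghr = prop$loghr)
       })
}

## -- the engine ----------------------------------------------------

#' Run Metropolis-Hastings over a model graph
#'
#' At each step a kernel is chosen by weight; only density components
#' touched by the kernel are recomputed.  Power-posterior targets are
#' supported: with `reference = NULL` the target is
#' `prior * likelihood^power`; with a reference density (generalized
#' stepping-stone path) it is `(prior * likelihood)^power *
#' reference^(1-power)`.
#'
#' @param graph a [model_graph()].
#' @param kernels list of kernels (see `kernel_*` constructors).
#' @param chain_length number of MH steps (>= 1).
#' @param log_every sampling interval for the trace.
#' @param rng_seed seed; identical seeds give identical traces.
#' @param init_state optional starting state (default: the specs' inits).
#' @param power inverse temperature applied to the likelihood side.
#' @param reference optional function `(state) -> log reference density`.
#' @param store_trees also keep sampled trees (at `log_every`).
#' @param tree_name name of the tree parameter, if any.
#' @return an `mcmc_trace`: list with `samples` (data.frame; `state`,
#'   `posterior`, `prior`, `likelihood`, scalar/vector columns, root
#'   height), `trees`, `acceptance`, `final_state`.
#' @export
run_mcmc <- function(graph, kernels, chain_length, log_every = 10,
                     rng_seed = NULL, init_state = NULL, power = 1,
                     reference = NULL, store_trees = FALSE,
                     tree_name = "tree") {
  stopifnot(chain_length >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  state <- if (is.null(init_state)) graph_init_state(graph) else init_state
  comp <- eval_components(graph, state)
  roles <- vapply(graph$components, `[[`, "", "role")
  lik_names <- names(comp)[roles == "likelihood"]
  prior_comp_names <- names(comp)[roles == "prior"]
  pprior <- param_log_prior(graph, state)
  refval <- if (is.null(reference)) 0 else reference(state)
  if (!all(is.finite(comp)) || !is.finite(pprior)) {
    bad <- c(names(comp)[!is.finite(comp)],
             if (!is.finite(pprior)) "parameter priors")
    stop("initial state has non-finite density in: ",
         paste(bad, collapse = ", "))
  }
  target <- function(pp, cp, rv) {
    lik <- sum(cp[lik_names])
    pri <- pp + sum(cp[prior_comp_names])
    if (is.null(reference)) pri + power * lik
    else power * (pri + lik) + (1 - power) * rv
  }
  cur <- target(pprior, comp, refval)
  has_tree <- !is.null(state[[tree_name]])
  wts <- vapply(kernels, `[[`, numeric(1), "weight")
  ## which components each kernel invalidates (precomputed)
  touch_map <- lapply(kernels, function(k)
    names(graph$components)[vapply(graph$components, function(cmp)
      any(cmp$depends %in% k$touched), TRUE)])
  n_out <- floor((chain_length - 1) / log_every) + 1L
  scalar_names <- names(graph$params)[
    vapply(graph$params, function(p) p$type != "tree", TRUE)]
  colnames_out <- unlist(lapply(scalar_names, function(nm) {
    len <- length(state[[nm]])
    if (len == 1L) nm else paste0(nm, ".", seq_len(len))
  }))
  out <- matrix(NA_real_, n_out,
                4L + length(colnames_out) + as.integer(has_tree))
  colnames(out) <- c("state", "posterior", "prior", "likelihood",
                     colnames_out, if (has_tree) "root_height")
  trees <- if (store_trees && has_tree) vector("list", n_out) else NULL
  n_prop <- n_acc <- setNames(numeric(length(kernels)),
                              vapply(kernels, `[[`, "", "name"))
  row <- 0L
  record <- function(it) {
    row <<- row + 1L
    vals <- unlist(lapply(scalar_names, function(nm) state[[nm]]))
    out[row, ] <<- c(it, pprior + sum(comp), pprior +
                       sum(comp[prior_comp_names]), sum(comp[lik_names]),
                     vals,
                     if (has_tree) state[[tree_name]]$heights[state[[tree_name]]$root])
    if (!is.null(trees)) trees[[row]] <<- state[[tree_name]]
  }
  record(1L)
  if (chain_length > 1) for (it in 2:chain_length) {
    ki <- sample.int(length(kernels), 1L, prob = wts)
    k <- kernels[[ki]]
    n_prop[ki] <- n_prop[ki] + 1
    prop <- k$propose(state)
    if (is.null(prop)) {            # no eligible target: auto-reject
      if (it %% log_every == 1L || log_every == 1L) record(it)
      next
    }
    newcomp <- comp
    touch <- touch_map[[ki]]
    ok <- TRUE
    if (length(touch)) {
      v <- tryCatch(eval_components(graph, prop$state, touch),
                    error = function(e) NULL)
      if (is.null(v) || any(is.nan(v))) ok <- FALSE else newcomp[touch] <- v
    }
    if (ok) {
      newpp <- param_log_prior(graph, prop$state)
      newref <- if (is.null(reference)) 0 else reference(prop$state)
      newtarget <- target(newpp, newcomp, newref)
      lratio <- newtarget - cur + prop$loghr
      alpha <- if (is.finite(lratio)) min(1, exp(lratio))
               else if (identical(lratio, Inf)) 1 else 0
      accepted <- is.finite(newtarget) && log(runif(1)) < lratio
    } else {
      alpha <- 0; accepted <- FALSE
    }
    if (accepted) {
      state <- prop$state
      comp <- newcomp
      pprior <- newpp
      refval <- newref
      cur <- newtarget
      n_acc[ki] <- n_acc[ki] + 1
    }
    if (!is.null(k$notify)) k$notify(accepted, alpha, prop$y)
    if (it %% log_every == 1L || log_every == 1L) record(it)
  }
  samples <- as.data.frame(out[seq_len(row), , drop = FALSE])
  structure(list(samples = samples,
                 trees = if (!is.null(trees)) trees[seq_len(row)],
                 acceptance = data.frame(kernel = names(n_prop),
                                         proposed = n_prop,
                                         accepted = n_acc,
                                         rate = ifelse(n_prop > 0,
                                                       n_acc / n_prop, NA)),
                 final_state = state),
            class = "mcmc_trace")
}

#' Effective sample size by initial monotone sequence truncation
#'
#' Geyer-style estimator: autocorrelations are summed over consecutive
#' pairs until a pair sum goes non-positive, enforcing monotone decay.
#'
#' @param x numeric trace column (>= 10 samples).
#' @return the ESS; for a zero-variance column, the sample count with
#'   attribute `zero_variance = TRUE`.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10) stop("need at least 10 samples")
  if (var(x) == 0 || !is.finite(var(x)))
    return(structure(as.numeric(n), zero_variance = TRUE))
  maxlag <- min(n - 2L, 2000L)
  rho <- as.numeric(acf(x, lag.max = maxlag, plot = FALSE,
                        demean = TRUE)$acf)[-1L]
  npair <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(npair) - 1L] + rho[2 * seq_len(npair)]
  s <- 0
  prev <- Inf
  for (g in gam) {
    if (g <= 0) break
    g <- min(g, prev)       # enforce monotone decrease
    s <- s + g
    prev <- g
  }
  max(1, n / (1 + 2 * s))
}

#' Hierarchical normal prior over a parameter group
#'
#' Members share a normal distribution on a transformed scale whose mean
#' and precision are themselves sampled (normal / gamma hyperpriors are
#' declared separately as ordinary parameters).
#'
#' @param mean_name,prec_name state names of the group mean and
#'   precision hyperparameters.
#' @param transform member scale (`"log"` maps positive members to the
#'   real line; the Jacobian is included).
#' @return a `log_prior` function for use in [param_spec()].
#' @export
hierarchical_normal_prior <- function(mean_name, prec_name,
                                      transform = c("log", "none")) {
  transform <- match.arg(transform)
  function(value, state) {
    m <- state[[mean_name]]
    sdv <- 1 / sqrt(state[[prec_name]])
    y <- transform_fwd(value, transform)
    dnorm(y, m, sdv, log = TRUE) - transform_logjac(value, transform)
  }
}
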