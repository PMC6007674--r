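## ------------------------------------------------------------------
## Discrete-trait (phylogeographic) diffusion with GLM-parameterized
## transition rates, BSSVS predictor inclusion and Bayes factors,
## Markov jump/reward expectations and stochastic mapping, and the
## multivariate Brownian continuous-trait likelihood.
## ------------------------------------------------------------------

#' Ordered state pairs of a K-state space
#' @param K number of states.
#' @param labels optional state labels.
#' @return data.frame with columns `from`, `to` (all i != j, row-major).
#' @export
ordered_pairs <- local({
  cache <- new.env(parent = emptyenv())
  function(K, labels = NULL) {
    key <- as.character(K)
    g <- cache[[key]]
    if (is.null(g)) {
      g <- expand.grid(to = seq_len(K), from = seq_len(K))[, 2:1]
      g <- g[g$from != g$to, ]
      rownames(g) <- NULL
      cache[[key]] <- g
    }
    if (!is.null(labels)) {
      g$from_label <- labels[g$from]
      g$to_label <- labels[g$to]
    }
    g
  }
})

#' Standardize a GLM predictor design
#'
#' Predictors flagged for log transform are logged first; every column is
#' then centered and scaled to unit variance, the convention under which
#' the default normal(0, 2) coefficient priors are weakly informative.
#'
#' @param X numeric matrix, one row per ordered state pair, one column
#'   per predictor.
#' @param log_transform logical vector per predictor.
#' @return standardized matrix.
#' @export
standardize_design <- function(X, log_transform = rep(FALSE, ncol(X))) {
  X <- as.matrix(X)
  for (p in seq_len(ncol(X))) {
    if (log_transform[p]) {
      if (any(X[, p] <= 0))
        stop("predictor ", p, " has non-positive values; cannot log-transform")
      X[, p] <- log(X[, p])
    }
    X[, p] <- (X[, p] - mean(X[, p])) / sd(X[, p])
  }
  X
}

#' GLM-parameterized trait rate matrix
#'
#' Off-diagonal relative rates are log-linear in the predictors:
#' `Lambda_ij = exp(sum_p delta_p beta_p x_{ij,p})`.  Binary inclusion
#' indicators `delta` implement spike-and-slab variable selection; the
#' asymmetric parameterization is the default (geographic flow is
#' directional), with an optional reversible variant multiplying by the
#' destination frequency.
#'
#' @param design standardized design matrix, `K(K-1)` rows in
#'   [ordered_pairs()] order, `P` columns.
#' @param beta coefficients, length `P`.
#' @param delta inclusion indicators in `{0,1}`, length `P`.
#' @param K number of states.
#' @param freqs optional stationary/root frequencies; required for the
#'   reversible variant, otherwise solved from the generator.
#' @param reversible multiply rates by destination frequency and verify
#'   detailed balance.
#' @param normalize one expected event per unit time (see [ctmc_model()]).
#' @return a `ctmc_model` with `K` states.
#' @export
glm_rate_matrix <- function(design, beta, delta, K, freqs = NULL,
                            reversible = FALSE, normalize = TRUE) {
  design <- as.matrix(design)
  if (nrow(design) != K * (K - 1L))
    stop("design must have K(K-1) rows of ordered pairs")
  if (length(beta) != ncol(design) || length(delta) != ncol(design))
    stop("beta and delta must have one entry per predictor")
  if (!all(delta %in% c(0, 1))) stop("delta must be binary")
  eta <- as.vector(design %*% (beta * delta))
  if (any(!is.finite(eta))) {
    p_bad <- which(!is.finite(design %*% diag(beta * delta, ncol(design))))
    stop("non-finite GLM linear predictor (predictor index ",
         paste(unique((p_bad - 1L) %/% nrow(design) + 1L), collapse = ","), ")")
  }
  pairs <- ordered_pairs(K)
  rates <- matrix(0, K, K)
  rates[cbind(pairs$from, pairs$to)] <- exp(eta)
  if (reversible) {
    if (is.null(freqs)) stop("reversible variant requires frequencies")
    rates <- rates * rep(freqs, each = K)
  }
  m <- ctmc_model(rates, freqs = freqs, normalize = normalize,
                  reversible = reversible)
  m$name <- "trait-GLM"
  m$glm <- list(design = design, beta = beta, delta = delta)
  m
}

#' BSSVS inclusion Bayes factor
#'
#' Posterior odds of predictor inclusion divided by prior odds:
#' `BF = [p/(1-p)] / [q/(1-q)]`.  A posterior frequency of exactly one
#' (saturated over finite samples) yields `+Inf` with attribute
#' `saturated = TRUE`.
#'
#' @param inclusion_posterior posterior inclusion frequency in `[0, 1]`.
#' @param prior_inclusion prior inclusion probability in `(0, 1)`.
#' @return the Bayes factor.
#' @export
bssvs_bayes_factor <- function(inclusion_posterior, prior_inclusion) {
  p <- inclusion_posterior; q <- prior_inclusion
  if (q <= 0 || q >= 1) stop("prior inclusion probability must be in (0,1)")
  if (p < 0 || p > 1) stop("posterior frequency must be in [0,1]")
  prior_odds <- q / (1 - q)
  if (p == 1) return(structure(Inf, saturated = TRUE))
  (p / (1 - p)) / prior_odds
}

## -- Markov jumps and rewards --------------------------------------

label_matrix <- function(model, L) {
  ## B[i,j] = actual rate Q_ij for labelled ordered pairs (i,j), else 0
  K <- model$K
  B <- matrix(0, K, K)
  L <- as.matrix(L)
  if (ncol(L) != 2L) stop("label set must be a 2-column (from,to) matrix")
  if (any(L[, 1L] == L[, 2L])) stop("labels must be ordered pairs i != j")
  B[L] <- model$Q[L]
  B
}

joint_restricted_expectation <- function(model, t, B) {
  ## M(t) = int_0^t P(s) B P(t-s) ds, via the eigensystem; near-equal
  ## eigenvalues use the t*exp(lambda t) limit.  Falls back to numerically
  ## integrated uniformization when the generator is defective.
  if (model$defective || is.null(model$eigen$inv))
    return(uniformized_restricted_expectation(model$Q, t, B))
  e <- model$eigen
  lam <- e$values
  C <- e$inv %*% B %*% e$vectors
  K <- model$K
  I <- matrix(0 + 0i, K, K)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      d <- lam[k] - lam[l]
      if (abs(d) < 1e-8) I[k, l] <- t * exp(lam[k] * t)
      else I[k, l] <- (exp(lam[k] * t) - exp(lam[l] * t)) / d
    }
  }
  Re(e$vectors %*% (C * I) %*% e$inv)
}

uniformized_restricted_expectation <- function(Q, t, B, tol = 1e-12) {
  ## int_0^t P(s) B P(t-s) ds =
  ##   sum_n Pois(n; mu t) (t/(n+1)) sum_{m=0..n} R^m B R^{n-m}
  K <- nrow(Q)
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(K) + Q / mu
  nmax <- max(10, ceiling(mu * t + 10 * sqrt(mu * t + 1)))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(K)
  for (n in seq_len(nmax)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  M <- matrix(0, K, K)
  for (n in 0:nmax) {
    w <- dpois(n, mu * t)
    if (w < tol && n > mu * t) break
    S <- matrix(0, K, K)
    for (m in 0:n) S <- S + Rpow[[m + 1L]] %*% B %*% Rpow[[n - m + 1L]]
    M <- M + w * t * S / (n + 1L)
  }
  M
}

#' Expected labelled Markov jumps on a branch
#'
#' Expected number of labelled state transitions on a branch of duration
#' `t` conditioned on the endpoint states:
#' `E[N_L | a, b, t] = sum_{(i,j) in L} Q_ij int_0^t P(s)_ai P(t-s)_jb ds
#'  / P(t)_ab`, evaluated in closed form through the eigensystem.
#'
#' @param model a `ctmc_model`.
#' @param t branch duration (already clock-scaled), non-negative.
#' @param a,b start and end states (1-based indices).
#' @param L label set: 2-column matrix of ordered pairs; default all
#'   ordered pairs (total jump count).
#' @return expected count (non-negative).
#' @export
expected_jumps <- function(model, t, a, b,
                           L = as.matrix(ordered_pairs(model$K)[, 1:2])) {
  if (t < 0) stop("branch duration must be non-negative")
  if (t == 0) {
    if (a != b) stop("impossible endpoints: a != b with t = 0")
    return(0)
  }
  Pt <- transition_probabilities(model, t)
  if (Pt[a, b] <= 0)
    stop(sprintf("endpoint pair (%d,%d) unreachable at t = %g", a, b, t))
  B <- label_matrix(model, L)
  ## jump-count integrand uses P(s)_{ai} Q_ij P(t-s)_{jb}: B already
  ## carries Q_ij on labelled pairs
  M <- joint_restricted_expectation_jump(model, t, B)
  max(M[a, b] / Pt[a, b], 0)
}

joint_restricted_expectation_jump <- function(model, t, B) {
  if (model$defective || is.null(model$eigen$inv))
    return(uniformized_jump_expectation(model$Q, t, B))
  e <- model$eigen
  lam <- e$values
  C <- e$inv %*% B %*% e$vectors
  K <- model$K
  I <- matrix(0 + 0i, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    d <- lam[k] - lam[l]
    I[k, l] <- if (abs(d) < 1e-8) t * exp(lam[k] * t)
               else (exp(lam[k] * t) - exp(lam[l] * t)) / d
  }
  Re(e$vectors %*% (C * I) %*% e$inv)
}

uniformized_jump_expectation <- function(Q, t, B, tol = 1e-14) {
  ## E[N_L 1{X_t=b} | X_0=a] by uniformization: labelled transitions of
  ## the subordinated chain (virtual self-jumps carry no label)
  K <- nrow(Q)
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(K) + Q / mu
  Bu <- B / mu                       # R-chain transition share on labels
  nmax <- max(20, ceiling(mu * t + 12 * sqrt(mu * t + 1)))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(K)
  for (n in seq_len(nmax)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  M <- matrix(0, K, K)
  for (n in seq_len(nmax)) {
    w <- dpois(n, mu * t)
    if (w < tol && n > mu * t) break
    S <- matrix(0, K, K)
    for (m in 0:(n - 1L))
      S <- S + Rpow[[m + 1L]] %*% Bu %*% Rpow[[n - m]]
    M <- M + w * S
  }
  M
}

#' Expected Markov reward (time spent in designated states) on a branch
#'
#' `E[time in reward_states | a, b, t]` via the analogous endpoint-
#' conditioned integral with `P(s)_ai P(t-s)_ib`; rewards over all K
#' states sum to the branch duration.
#'
#' @inheritParams expected_jumps
#' @param reward_states integer vector of states earning reward.
#' @return expected time, in `[0, t]`.
#' @export
expected_rewards <- function(model, t, a, b, reward_states) {
  if (t < 0) stop("branch duration must be non-negative")
  if (t == 0) return(0)
  Pt <- transition_probabilities(model, t)
  if (Pt[a, b] <= 0)
    stop(sprintf("endpoint pair (%d,%d) unreachable at t = %g", a, b, t))
  B <- matrix(0, model$K, model$K)
  diag(B)[reward_states] <- 1
  M <- joint_restricted_expectation(model, t, B)
  min(max(M[a, b] / Pt[a, b], 0), t)
}

## -- stochastic mapping --------------------------------------------

sample_path_rejection <- function(Q, a, b, t, max_tries = 50L) {
  K <- nrow(Q)
  for (try in seq_len(max_tries)) {
    s <- a; time <- 0
    events <- list()
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      time <- time + rexp(1, rate)
      if (time >= t) break
      j <- sample.int(K, 1L, prob = Q[s, ] * (seq_len(K) != s))
      events[[length(events) + 1L]] <- c(time, s, j)
      s <- j
    }
    if (s == b)
      return(if (length(events))
               do.call(rbind, events) else matrix(numeric(0), 0, 3))
  }
  NULL
}

sample_path_uniformization <- function(Q, a, b, t) {
  K <- nrow(Q)
  mu <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(K) + Q / mu
  Pt_ab <- as.matrix(Matrix::expm(Q * t))[a, b]
  nmax <- max(20, ceiling(mu * t + 12 * sqrt(mu * t + 1)))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(K)
  for (n in seq_len(nmax)) Rpow[[n + 1L]] <- Rpow[[n]] %*% R
  pn <- vapply(0:nmax, function(n) dpois(n, mu * t) * Rpow[[n + 1L]][a, b],
               numeric(1)) / Pt_ab
  pn[!is.finite(pn)] <- 0
  n <- sample.int(nmax + 1L, 1L, prob = pn) - 1L
  states <- integer(n + 1L)
  states[1L] <- a
  if (n > 0) {
    for (m in seq_len(n)) {
      ## forward sampling conditioned on endpoint b after n total steps
      w <- R[states[m], ] * Rpow[[n - m + 1L]][, b]
      states[m + 1L] <- sample.int(K, 1L, prob = w)
    }
    states[n + 1L] <- b
  }
  times <- sort(runif(n, 0, t))
  keep <- which(states[-1L] != states[-(n + 1L)])
  if (!length(keep)) return(matrix(numeric(0), 0, 3))
  cbind(times[keep], states[keep], states[keep + 1L])
}

#' Stochastic mapping of a discrete trait on a tree
#'
#' Draws a full realization of the trait transition process conditioned
#' on the observed tip states: ancestral node states are sampled from
#' their conditional distributions, then each branch receives an
#' endpoint-conditioned path (rejection sampling with a uniformization
#' fallback, so termination is guaranteed).
#'
#' @param tree a `timetree`.
#' @param model a `ctmc_model` over the trait states.
#' @param tip_states named character vector taxon -> state label (`"?"`
#'   allowed), or integer states.
#' @param levels state labels (required when `tip_states` is character).
#' @param clock_rate trait clock rate scaling branch durations.
#' @param rng_seed optional seed for exact reproducibility.
#' @return a `stochastic_map`: list with `node_states` (integer per
#'   node), `events` (per non-root node, matrix with columns time-from-
#'   parent (clock-scaled), from, to) and `n_jumps`.
#' @export
stochastic_map <- function(tree, model, tip_states, levels = NULL,
                           clock_rate = 1, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  K <- model$K
  if (is.character(tip_states)) {
    if (is.null(levels)) stop("levels required for character tip states")
    tp_arr <- trait_tip_partials(tip_states[tree$tip_label], levels)
    tipp <- t(tp_arr[, 1L, ])
  } else {
    tipp <- matrix(0, tree$ntip, K)
    tipp[cbind(seq_len(tree$ntip), tip_states[tree$tip_label])] <- 1
  }
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  bl <- branch_length(tree, nonroot) * clock_rate
  Parr <- transition_prob_array(model, bl)
  P <- array(0, c(K, K, tree$nnode))
  P[, , nonroot] <- Parr
  partials <- peel_partials_cpp(postorder_nodes(tree), tree$children,
                                tree$ntip, tree$nnode, K, as.vector(P), tipp)
  node_states <- integer(tree$nnode)
  wroot <- model$freqs * partials[tree$root, ]
  node_states[tree$root] <- sample.int(K, 1L, prob = wroot)
  for (v in rev(postorder_nodes(tree))) {
    for (ch in tree$children[v, ]) {
      w <- P[node_states[v], , ch] * partials[ch, ]
      node_states[ch] <- sample.int(K, 1L, prob = w)
    }
  }
  events <- vector("list", tree$nnode)
  njump <- 0L
  for (v in nonroot) {
    a <- node_states[tree$parent[v]]
    b <- node_states[v]
    t_br <- branch_length(tree, v) * clock_rate
    path <- if (t_br == 0) {
      matrix(numeric(0), 0, 3)
    } else {
      p <- sample_path_rejection(model$Q, a, b, t_br)
      if (is.null(p)) sample_path_uniformization(model$Q, a, b, t_br) else p
    }
    colnames(path) <- c("time", "from", "to")
    events[[v]] <- path
    njump <- njump + nrow(path)
  }
  structure(list(node_states = node_states, events = events,
                 n_jumps = njump, levels = levels),
            class = "stochastic_map")
}

#' Count labelled jumps in a realization
#' @param map a `stochastic_map` (or simulated trait history).
#' @param L 2-column matrix of ordered pairs; default all.
#' @return total labelled jump count over all branches.
#' @export
realized_jump_count <- function(map, L = NULL) {
  n <- 0L
  for (ev in map$events) {
    if (is.null(ev) || nrow(ev) == 0) next
    if (is.null(L)) n <- n + nrow(ev)
    else {
      key <- paste(ev[, 2L], ev[, 3L])
      n <- n + sum(key %in% paste(L[, 1L], L[, 2L]))
    }
  }
  n
}

## -- multivariate Brownian trait likelihood ------------------------

#' Brownian trait model
#' @param Sigma d x d positive-definite diffusion variance per unit time.
#' @param root_mean root state mean (length d); ignored for the flat root.
#' @param root_var scalar multiplier of `Sigma` for the root prior
#'   variance: `Inf` (default) integrates the root against an improper
#'   flat prior (REML-style), `0` fixes the root at `root_mean`.
#' @return a `brownian_model`.
#' @export
brownian_model <- function(Sigma, root_mean = NULL, root_var = Inf) {
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  if (is.null(root_mean)) root_mean <- rep(0, d)
  structure(list(d = d, Sigma = Sigma, root_mean = as.numeric(root_mean),
                 root_var = root_var),
            class = "brownian_model")
}

logdet_chol <- function(S) 2 * sum(log(diag(chol(S))))

ldmvnorm0 <- function(x, v, Sigma, Sinv, ldetS) {
  ## density of N(0, v * Sigma) at x
  d <- length(x)
  -0.5 * (d * log(2 * pi * v) + ldetS + sum(x * (Sinv %*% x)) / v)
}

#' Brownian motion log-likelihood of tip traits on a time tree
#'
#' Log density of the tip trait matrix under Brownian diffusion along
#' the tree (between-taxon covariance = shared path length times
#' `Sigma`), computed by a linear-time post-order contrast recursion.
#' With the default improper flat root prior the root state is
#' integrated out (the result is the REML/contrast likelihood); a
#' conjugate normal or fixed root is also supported.
#'
#' @param tree a `timetree`.
#' @param bm a `brownian_model`.
#' @param tip_traits numeric matrix, one row per taxon (rownames =
#'   labels), `d` columns.
#' @return log-likelihood.
#' @export
brownian_loglik <- function(tree, bm, tip_traits) {
  tip_traits <- as.matrix(tip_traits)
  if (ncol(tip_traits) != bm$d) stop("trait dimension mismatch")
  ord <- match(tree$tip_label, rownames(tip_traits))
  if (anyNA(ord)) stop("missing trait rows for some tips")
  Y <- tip_traits[ord, , drop = FALSE]
  Sinv <- solve(bm$Sigma)
  ldetS <- logdet_chol(bm$Sigma)
  mean_v <- matrix(0, tree$nnode, bm$d)
  extra_v <- numeric(tree$nnode)
  mean_v[seq_len(tree$ntip), ] <- Y
  ll <- 0
  for (v in postorder_nodes(tree)) {
    c1 <- tree$children[v, 1L]; c2 <- tree$children[v, 2L]
    V1 <- branch_length(tree, c1) + extra_v[c1]
    V2 <- branch_length(tree, c2) + extra_v[c2]
    contrast <- mean_v[c1, ] - mean_v[c2, ]
    ll <- ll + ldmvnorm0(contrast, V1 + V2, bm$Sigma, Sinv, ldetS)
    mean_v[v, ] <- (V2 * mean_v[c1, ] + V1 * mean_v[c2, ]) / (V1 + V2)
    extra_v[v] <- V1 * V2 / (V1 + V2)
  }
  if (is.finite(bm$root_var)) {
    vr <- extra_v[tree$root] + bm$root_var
    ll <- ll + ldmvnorm0(mean_v[tree$root, ] - bm$root_mean, vr,
                         bm$Sigma, Sinv, ldetS)
  }
  ll
}
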