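## Independent oracles used across the suite.  These deliberately avoid
## the package's own computational paths: likelihoods by exhaustive
## enumeration, jump/reward expectations by uniformization series,
## densities by dense multivariate-normal algebra.

## exhaustive pruning oracle: sum over all internal-state assignments
enumerate_loglik <- function(tree, pm, model = pm$model,
                             clock_rate = pm$clock_rate) {
  K <- model$K
  ord <- match(tree$tip_label, pm$patterns$taxa)
  internal <- (tree$ntip + 1L):tree$nnode
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  total <- 0
  for (p in seq_along(pm$patterns$weights)) {
    site_lik <- 0
    for (c in seq_len(pm$site_rates$k)) {
      Pm <- lapply(seq_len(tree$nnode), function(v) {
        if (v == tree$root) return(NULL)
        transition_probabilities(model, branch_length(tree, v) *
                                   clock_rate * pm$site_rates$rates[c])
      })
      grid <- as.matrix(expand.grid(rep(list(seq_len(K)),
                                        length(internal))))
      s <- 0
      for (g in seq_len(nrow(grid))) {
        assign_state <- integer(tree$nnode)
        assign_state[internal] <- grid[g, ]
        prod_lik <- model$freqs[assign_state[tree$root]]
        for (v in nonroot) {
          pv <- assign_state[tree$parent[v]]
          if (v <= tree$ntip) {
            tipp <- pm$tip_partials[, p, ord[v]]
            prod_lik <- prod_lik * sum(Pm[[v]][pv, ] * tipp)
          } else {
            prod_lik <- prod_lik * Pm[[v]][pv, assign_state[v]]
          }
        }
        s <- s + prod_lik
      }
      site_lik <- site_lik + pm$site_rates$probs[c] * s
    }
    total <- total + pm$patterns$weights[p] * log(site_lik)
  }
  total
}

## uniformization-series oracle for endpoint-conditioned jump counts
oracle_expected_jumps <- function(Q, t, a, b, L) {
  K <- nrow(Q)
  mu <- max(-diag(Q)) * 1.1 + 1e-9
  R <- diag(K) + Q / mu
  BL <- matrix(0, K, K)
  BL[L] <- R[L]
  nmax <- ceiling(mu * t + 15 * sqrt(mu * t + 1)) + 20
  Rp <- vector("list", nmax + 1)
  Rp[[1]] <- diag(K)
  for (n in seq_len(nmax)) Rp[[n + 1]] <- Rp[[n]] %*% R
  M <- matrix(0, K, K)
  for (n in seq_len(nmax)) {
    S <- matrix(0, K, K)
    for (m in 0:(n - 1)) S <- S + Rp[[m + 1]] %*% BL %*% Rp[[n - m]]
    M <- M + dpois(n, mu * t) * S
  }
  Pt <- matrix(0, K, K)
  for (n in 0:nmax) Pt <- Pt + dpois(n, mu * t) * Rp[[n + 1]]
  M[a, b] / Pt[a, b]
}

## uniformization-series oracle for endpoint-conditioned rewards
oracle_expected_rewards <- function(Q, t, a, b, states) {
  K <- nrow(Q)
  mu <- max(-diag(Q)) * 1.1 + 1e-9
  R <- diag(K) + Q / mu
  D <- diag(as.numeric(seq_len(K) %in% states))
  nmax <- ceiling(mu * t + 15 * sqrt(mu * t + 1)) + 20
  Rp <- vector("list", nmax + 1)
  Rp[[1]] <- diag(K)
  for (n in seq_len(nmax)) Rp[[n + 1]] <- Rp[[n]] %*% R
  M <- matrix(0, K, K)
  for (n in 0:nmax) {
    S <- matrix(0, K, K)
    for (m in 0:n) S <- S + Rp[[m + 1]] %*% D %*% Rp[[n - m + 1]]
    M <- M + dpois(n, mu * t) * t * S / (n + 1)
  }
  Pt <- matrix(0, K, K)
  for (n in 0:nmax) Pt <- Pt + dpois(n, mu * t) * Rp[[n + 1]]
  M[a, b] / Pt[a, b]
}

## dense multivariate-normal log density
ldmvnorm_dense <- function(x, mean, V) {
  ch <- chol(V)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

## dense Brownian oracle: flat root integrated via tip differences
brownian_dense_loglik <- function(tree, Sigma, Y, root_var = Inf,
                                  root_mean = NULL) {
  C <- ape::vcv.phylo(timetree_to_phylo(tree))
  C <- C[rownames(Y), rownames(Y)]
  n <- nrow(Y); d <- ncol(Y)
  if (is.infinite(root_var)) {
    Cd <- outer(2:n, 2:n, Vectorize(function(i, j)
      C[i, j] - C[i, 1] - C[1, j] + C[1, 1]))
    D <- Y[-1, , drop = FALSE] - matrix(Y[1, ], n - 1, d, byrow = TRUE)
    ldmvnorm_dense(as.vector(D), 0, kronecker(Sigma, Cd))
  } else {
    V <- kronecker(Sigma, C + root_var)
    mu <- rep(root_mean, each = n)
    ldmvnorm_dense(as.vector(Y), mu, V)
  }
}

## closed-form conjugate normal-mean marginal likelihood
conjugate_logml <- function(y, sigma, mu0, tau0) {
  n <- length(y)
  V <- diag(sigma^2, n) + tau0^2
  ldmvnorm_dense(y, rep(mu0, n), V)
}

## small fixed fixtures
fixture_tree5 <- function(seed = 42)
  simulate_coalescent_tree(rep(0, 5), constant_demography(1), seed = seed)

fixture_serial_tree <- function(n = 6, span = 2, seed = 7) {
  set.seed(seed)
  h <- runif(n, 0, span); h <- h - min(h)
  simulate_coalescent_tree(h, constant_demography(1))
}

random_reversible_model <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- rgamma(K, 5, 1); freqs <- freqs / sum(freqs)
  ex <- matrix(0, K, K)
  ex[upper.tri(ex)] <- runif(K * (K - 1) / 2, 0.2, 2)
  ex <- ex + t(ex)
  ctmc_model(ex * rep(freqs, each = K), freqs = freqs, reversible = TRUE)
}
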