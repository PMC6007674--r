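test_that("GLM rate matrix follows the log-linear parameterization", {
  K <- 4
  pairs <- ordered_pairs(K)
  P <- 2
  X <- matrix(0, nrow(pairs), P)
  ## all beta zero: equal rates
  m0 <- glm_rate_matrix(X, c(0, 0), c(1, 1), K, normalize = FALSE)
  off <- m0$Q[row(m0$Q) != col(m0$Q)]
  expect_true(all(abs(off - 1) < 1e-12))
  ## single predictor hitting one ordered pair: rate doubles
  X1 <- X
  X1[pairs$from == 1 & pairs$to == 2, 1] <- 1
  m1 <- glm_rate_matrix(X1, c(log(2), 0), c(1, 1), K, normalize = FALSE)
  expect_equal(m1$Q[1, 2], 2)
  expect_equal(m1$Q[2, 1], 1)
  expect_equal(m1$Q[3, 4], 1)
  ## indicator masking: delta = 0 wipes out arbitrary beta
  m2 <- glm_rate_matrix(X1, c(99, -99), c(0, 0), K, normalize = FALSE)
  expect_equal(m2$Q, m0$Q)
  expect_error(glm_rate_matrix(X1, c(Inf, 0), c(1, 1), K), "non-finite")
})

test_that("design standardization centers, scales and logs", {
  set.seed(1)
  X <- cbind(a = exp(rnorm(12, 2)), b = rnorm(12))
  S <- standardize_design(X, log_transform = c(TRUE, FALSE))
  expect_lt(max(abs(colMeans(S))), 1e-12)
  expect_equal(unname(apply(S, 2, sd)), c(1, 1))
  expect_equal(unname(S[, 1]), unname(scale(log(X[, 1]))[, 1]))
  expect_error(standardize_design(cbind(c(-1, 2, 3)), log_transform = TRUE),
               "non-positive")
})

test_that("BSSVS Bayes factor is the posterior-to-prior odds ratio", {
  expect_equal(bssvs_bayes_factor(0.5, 0.5), 1)
  expect_equal(bssvs_bayes_factor(0.75, 0.5), 3)
  expect_equal(bssvs_bayes_factor(0.6, 0.2), 6)
  bf <- bssvs_bayes_factor(1, 0.5)
  expect_true(is.infinite(bf) && bf > 0)
  expect_true(attr(bf, "saturated"))
  expect_error(bssvs_bayes_factor(0.5, 1), "in \\(0,1\\)")
})

test_that("expected jumps match the uniformization oracle", {
  set.seed(12)
  for (K in c(2, 3)) {
    rates <- matrix(runif(K * K, 0.3, 1.5), K, K); diag(rates) <- 0
    m <- ctmc_model(rates)
    L <- as.matrix(ordered_pairs(K)[, 1:2])
    for (t in c(0.3, 1.1)) {
      P <- transition_probabilities(m, t)
      for (a in 1:K) for (b in 1:K) {
        expect_lt(abs(expected_jumps(m, t, a, b, L) -
                      oracle_expected_jumps(m$Q, t, a, b, L)), 1e-8)
      }
    }
  }
  expect_equal(expected_jumps(ctmc_model(matrix(c(0, 1, 1, 0), 2, 2)),
                              0, 1, 1), 0)
})

test_that("marginal total jumps equal elapsed time for a unit-rate chain", {
  set.seed(5)
  K <- 4
  rates <- matrix(runif(K * K, 0.2, 2), K, K); diag(rates) <- 0
  m <- ctmc_model(rates)   # normalized: one event per unit time
  t <- 0.9
  P <- transition_probabilities(m, t)
  tot <- 0
  for (a in 1:K) for (b in 1:K)
    if (P[a, b] > 0)
      tot <- tot + m$freqs[a] * P[a, b] * expected_jumps(m, t, a, b)
  expect_equal(tot, t, tolerance = 1e-9)
})

test_that("jump expectations are additive over label partitions", {
  set.seed(6)
  K <- 3
  rates <- matrix(runif(K * K, 0.3, 1.2), K, K); diag(rates) <- 0
  m <- ctmc_model(rates)
  all_pairs <- as.matrix(ordered_pairs(K)[, 1:2])
  part1 <- all_pairs[1:3, , drop = FALSE]
  part2 <- all_pairs[4:6, , drop = FALSE]
  t <- 0.8
  e_all <- expected_jumps(m, t, 1, 2, all_pairs)
  expect_lt(abs(expected_jumps(m, t, 1, 2, part1) +
                expected_jumps(m, t, 1, 2, part2) - e_all), 1e-10)
})

test_that("rewards conserve branch duration and match the oracle", {
  set.seed(7)
  K <- 3
  rates <- matrix(runif(K * K, 0.4, 1.4), K, K); diag(rates) <- 0
  m <- ctmc_model(rates)
  t <- 1.2
  expect_equal(expected_rewards(m, t, 1, 3, 1:K), t, tolerance = 1e-9)
  for (s in 1:K)
    expect_lt(abs(expected_rewards(m, t, 2, 1, s) -
                  oracle_expected_rewards(m$Q, t, 2, 1, s)), 1e-8)
  ## vanishing branch: reward concentrates in the endpoint state
  expect_equal(expected_rewards(m, 1e-8, 2, 2, 2) / 1e-8, 1,
               tolerance = 1e-4)
})

test_that("stochastic mapping is reproducible and endpoint-consistent", {
  set.seed(9)
  K <- 3
  levels <- c("X", "Y", "Z")
  rates <- matrix(runif(K * K, 0.3, 1.5), K, K); diag(rates) <- 0
  m <- ctmc_model(rates)
  tr <- fixture_serial_tree(6)
  sim <- simulate_discrete_trait(tr, m, clock_rate = 1.5, levels = levels,
                                 seed = 4)
  m1 <- stochastic_map(tr, m, sim$tip_states, levels, clock_rate = 1.5,
                       rng_seed = 99)
  m2 <- stochastic_map(tr, m, sim$tip_states, levels, clock_rate = 1.5,
                       rng_seed = 99)
  expect_identical(m1$events, m2$events)
  expect_identical(m1$node_states, m2$node_states)
  ## realization consistent with sampled endpoints on every branch
  for (v in setdiff(seq_len(tr$nnode), tr$root)) {
    ev <- m1$events[[v]]
    a <- m1$node_states[tr$parent[v]]
    states <- if (nrow(ev)) unname(c(ev[, "from"], ev[nrow(ev), "to"])) else a
    expect_equal(states[1], a)
    expect_equal(if (nrow(ev)) unname(ev[nrow(ev), "to"]) else a,
                 m1$node_states[v])
    ## tips must match the observed data
    if (v <= tr$ntip)
      expect_equal(levels[m1$node_states[v]],
                   unname(sim$tip_states[tr$tip_label[v]]))
  }
})

test_that("endpoint-conditioned path sampler reproduces analytic moments", {
  set.seed(15)
  K <- 3
  rates <- matrix(runif(K * K, 0.3, 1.5), K, K); diag(rates) <- 0
  m <- ctmc_model(rates)
  t <- 0.9; a <- 1; b <- 2
  n <- 20000
  nj <- numeric(n); rw <- numeric(n)
  for (i in seq_len(n)) {
    p <- phylomcmc:::sample_path_rejection(m$Q, a, b, t)
    if (is.null(p)) p <- phylomcmc:::sample_path_uniformization(m$Q, a, b, t)
    nj[i] <- nrow(p)
    st <- c(a, p[, 3]); times <- c(0, p[, 1], t)
    rw[i] <- sum(diff(times)[st == 1])
  }
  ej <- expected_jumps(m, t, a, b)
  er <- expected_rewards(m, t, a, b, 1)
  expect_lt(abs(mean(nj) - ej), 3 * sd(nj) / sqrt(n))
  expect_lt(abs(mean(rw) - er), 3 * sd(rw) / sqrt(n))
})

test_that("Brownian likelihood equals the dense MVN evaluation", {
  set.seed(20)
  tr <- fixture_serial_tree(4, seed = 2)
  S <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  bm <- brownian_model(S)
  Y <- simulate_continuous_trait(tr, bm, seed = 3)
  ll <- brownian_loglik(tr, bm, Y)
  expect_equal(ll, brownian_dense_loglik(tr, S, Y), tolerance = 1e-10)
  ## conjugate normal root
  bm2 <- brownian_model(S, root_mean = c(0.5, -1), root_var = 0.7)
  expect_equal(brownian_loglik(tr, bm2, Y),
               brownian_dense_loglik(tr, S, Y, root_var = 0.7,
                                     root_mean = c(0.5, -1)),
               tolerance = 1e-10)
  expect_error(brownian_model(matrix(c(1, 2, 2, 1), 2, 2)), "positive definite")
})

test_that("near-star tree with a fixed root factorizes into independent normals", {
  ## binary tree with negligible internal branches approximates a star
  tr <- parse_newick("((A:1,B:1.000000001):1e-9,C:1.0000000005);")
  bm <- brownian_model(matrix(2), root_mean = 0.3, root_var = 0)
  Y <- matrix(c(0.1, -1, 0.7), dimnames = list(c("A", "B", "C"), NULL))
  ll <- brownian_loglik(tr, bm, Y)
  indep <- sum(dnorm(Y[, 1], 0.3, sqrt(2 * 1), log = TRUE))
  expect_equal(ll, indep, tolerance = 1e-6)
})

test_that("Brownian scaling identity holds in closed form", {
  set.seed(25)
  tr <- fixture_serial_tree(6, seed = 5)
  S <- matrix(c(1, 0.3, 0.3, 0.6), 2, 2)
  Y <- simulate_continuous_trait(tr, brownian_model(S), seed = 6)
  n <- tr$ntip; d <- 2
  ll1 <- brownian_loglik(tr, brownian_model(S), Y)
  ll2 <- brownian_loglik(tr, brownian_model(2 * S), Y)
  ## ll(c Sigma) = const - ((n-1)d/2) log c - Q/c: predict c = 4 from c = 1, 2
  Q <- 2 * (ll2 - ll1 + (n - 1) * d / 2 * log(2))
  pred4 <- ll1 + Q - Q / 4 - (n - 1) * d / 2 * log(4)
  expect_equal(brownian_loglik(tr, brownian_model(4 * S), Y), pred4,
               tolerance = 1e-8)
})

test_that("trait pruning reuses the sequence engine at larger state counts", {
  set.seed(30)
  for (K in c(3, 8)) {
    levels <- paste0("s", seq_len(K))
    m <- random_reversible_model(K, seed = K + 1)
    tr <- fixture_tree5(seed = K)
    sim <- simulate_discrete_trait(tr, m, clock_rate = 1, levels = levels,
                                   seed = K)
    tp <- trait_tip_partials(sim$tip_states[tr$tip_label], levels)
    pats <- list(patterns = NULL, weights = 1, taxa = tr$tip_label)
    pm <- partition_model(pats, m, clock_rate = 1, tip_partials = tp)
    ll <- prune_loglik(tr, pm)
    expect_lt(abs(ll - enumerate_loglik(tr, pm)) /
                abs(enumerate_loglik(tr, pm)), 1e-10)
  }
})
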