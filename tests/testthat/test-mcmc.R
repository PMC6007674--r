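test_that("prior-only chains recover prior moments for every kernel type", {
  ## exponential(1) prior via the multiplicative scale kernel
  g <- model_graph(
    params = list(param_spec("x", 1, function(v, s) dexp(v, 1, log = TRUE),
                             "log")),
    components = list())
  tr <- run_mcmc(g, list(kernel_scale("x", delta = 2)), 3e4, log_every = 3,
                 rng_seed = 1)
  x <- tr$samples$x
  n_eff <- ess(x)
  expect_lt(abs(mean(x) - 1), 3 * sd(x) / sqrt(n_eff))
  expect_lt(abs(var(x) - 1), 0.25)

  ## normal prior via the random-walk kernel
  g2 <- model_graph(
    params = list(param_spec("m", 0, function(v, s)
      dnorm(v, 2, 0.7, log = TRUE))),
    components = list())
  tr2 <- run_mcmc(g2, list(kernel_walk("m", sd = 1.2)), 2e4, log_every = 2,
                  rng_seed = 2)
  m <- tr2$samples$m
  expect_lt(abs(mean(m) - 2), 3 * sd(m) / sqrt(ess(m)))
  expect_lt(abs(sd(m) - 0.7), 0.1)

  ## Bernoulli(q) inclusion indicators via bit flips
  q <- 0.3
  g3 <- model_graph(
    params = list(param_spec("d", c(1, 1, 1), function(v, s)
      sum(v * log(q) + (1 - v) * log(1 - q)), type = "indicator")),
    components = list())
  tr3 <- run_mcmc(g3, list(kernel_bitflip("d")), 2e4, log_every = 2,
                  rng_seed = 3)
  freq <- mean(as.matrix(tr3$samples[, c("d.1", "d.2", "d.3")]))
  expect_lt(abs(freq - q), 0.03)
})

test_that("degenerate chains and determinism contracts hold", {
  g <- model_graph(
    params = list(param_spec("x", 1, function(v, s) dexp(v, 1, log = TRUE),
                             "log")),
    components = list())
  ## chain of length 1: the initial state only
  tr1 <- run_mcmc(g, list(kernel_scale("x")), 1, rng_seed = 1)
  expect_equal(nrow(tr1$samples), 1L)
  expect_equal(tr1$samples$x, 1)
  ## same seed, same trace
  a <- run_mcmc(g, list(kernel_scale("x")), 2000, log_every = 5, rng_seed = 9)
  b <- run_mcmc(g, list(kernel_scale("x")), 2000, log_every = 5, rng_seed = 9)
  expect_identical(a$samples, b$samples)
  ## a state violating the prior support errors informatively
  g_bad <- model_graph(
    params = list(param_spec("x", -1, function(v, s)
      dexp(v, 1, log = TRUE), "log")),
    components = list())
  expect_error(run_mcmc(g_bad, list(kernel_scale("x")), 10),
               "non-finite")
})

test_that("adaptive multivariate kernel beats single-parameter kernels on
           a correlated target", {
  ## target: bivariate normal, rho = 0.9, expressed as prior-only graph
  rho <- 0.9
  Sinv <- solve(matrix(c(1, rho, rho, 1), 2, 2))
  g <- model_graph(
    params = list(
      param_spec("x1", 0, function(v, s) {
        z <- c(v, s$x2); -0.5 * sum(z * (Sinv %*% z))
      }),
      param_spec("x2", 0, function(v, s) 0)
    ),
    components = list())
  steps <- 3e4
  tr_s <- run_mcmc(g, list(kernel_walk("x1", sd = 0.7),
                           kernel_walk("x2", sd = 0.7)),
                   steps, log_every = 5, rng_seed = 4)
  ad <- kernel_adaptive_mvn(c("x1", "x2"), g, start_adapt = 500)
  tr_a <- run_mcmc(g, list(ad), steps, log_every = 5, rng_seed = 4)
  ess_s <- min(ess(tr_s$samples$x1), ess(tr_s$samples$x2))
  ess_a <- min(ess(tr_a$samples$x1), ess(tr_a$samples$x2))
  expect_gt(ess_a / ess_s, 3)
  ## adaptation drives acceptance into the efficient band
  acc <- tr_a$acceptance$rate[tr_a$acceptance$kernel == "adaptive_mvn"]
  expect_gt(acc, 0.1)
  expect_lt(acc, 0.5)
  ## learned covariance picks up the correlation
  learned <- ad$env$cov
  expect_gt(learned[1, 2] / sqrt(learned[1, 1] * learned[2, 2]), 0.7)
})

test_that("adaptive kernel respects transform Jacobians", {
  ## two positive parameters, independent exponential priors; the
  ## adaptive kernel proposes on log scale and must keep the prior exact
  g <- model_graph(
    params = list(
      param_spec("a", 1, function(v, s) dexp(v, 1, log = TRUE), "log"),
      param_spec("b", 1, function(v, s) dexp(v, 2, log = TRUE), "log")),
    components = list())
  tr <- run_mcmc(g, list(kernel_adaptive_mvn(c("a", "b"), g,
                                             start_adapt = 300)),
                 4e4, log_every = 4, rng_seed = 6)
  a <- tr$samples$a; b <- tr$samples$b
  expect_lt(abs(mean(a) - 1), 3 * sd(a) / sqrt(ess(a)))
  expect_lt(abs(mean(b) - 0.5), 3 * sd(b) / sqrt(ess(b)))
})

test_that("tree moves preserve invariants and reach all topologies", {
  set.seed(11)
  tr <- fixture_serial_tree(6, seed = 3)
  movers <- list(function(t) move_root_scale(t, 0.5),
                 move_uniform_height,
                 move_narrow_exchange,
                 function(t) move_subtree_slide(t, 0.5),
                 move_wilson_balding)
  for (mv in movers) {
    cur <- tr
    for (i in 1:300) {
      prop <- mv(cur)
      if (is.null(prop)) next
      expect_silent(validate_timetree(prop$tree))
      expect_true(is.finite(prop$loghr))
      cur <- prop$tree
    }
    ## tip heights are never moved
    expect_equal(cur$heights[seq_len(cur$ntip)],
                 tr$heights[seq_len(tr$ntip)])
  }
  ## narrow exchange on 3 tips proposes an alternative resolution
  t3 <- parse_newick("((A:1,B:1):1,C:2);")
  seen <- character()
  for (i in 1:50) {
    p <- move_narrow_exchange(t3)
    if (!is.null(p)) {
      k <- phylomcmc:::clade_keys(p$tree, c("A", "B", "C"))$keys
      seen <- union(seen, k[5])  # cherry clade of the proposal
    }
  }
  expect_true(length(seen) >= 1 && !("1,2" %in% seen))
})

test_that("hierarchical normal prior links group members through
           sampled hyperparameters", {
  hp <- hierarchical_normal_prior("hmean", "hprec", transform = "log")
  g <- model_graph(
    params = list(
      param_spec("hmean", 0, function(v, s) dnorm(v, 0, 1, log = TRUE)),
      param_spec("hprec", 1, function(v, s)
        dgamma(v, 2, rate = 2, log = TRUE), "log"),
      param_spec("r1", 1, hp, "log"),
      param_spec("r2", 1, hp, "log")),
    components = list())
  ks <- list(kernel_walk("hmean", sd = 0.8), kernel_scale("hprec"),
             kernel_scale("r1"), kernel_scale("r2"))
  tr <- run_mcmc(g, ks, 4e4, log_every = 4, rng_seed = 7)
  s <- tr$samples
  ## marginal of log r_i: mean 0; variance = Var(hmean) + E[1/prec]
  ## with prec ~ Gamma(2, rate 2): E[1/prec] = 2/(2-1) = 2, total 3
  lr <- log(c(s$r1, s$r2))
  expect_lt(abs(mean(lr)), 0.25)
  expect_lt(abs(var(lr) - 3), 0.8)
  ## members correlate through the shared mean
  expect_gt(cor(log(s$r1), log(s$r2)), 0.2)
})

test_that("partitions share linked parameters and separate unlinked ones", {
  ## two alignment partitions on one tree: clock linked (one node),
  ## kappas unlinked under a shared hierarchical prior
  set.seed(17)
  tr <- fixture_serial_tree(8, seed = 9)
  freqs <- c(0.3, 0.2, 0.25, 0.25)
  aln1 <- simulate_sequences(tr, build_hky(freqs, 2), clock_rate = 0.5,
                             n_sites = 120)
  aln2 <- simulate_sequences(tr, build_hky(freqs, 8), clock_rate = 0.5,
                             n_sites = 120)
  pm1 <- partition_model(compress_patterns(aln1), build_hky(freqs, 2))
  pm2 <- partition_model(compress_patterns(aln2), build_hky(freqs, 2))
  hp <- hierarchical_normal_prior("lk_mean", "lk_prec", transform = "log")
  g <- model_graph(
    params = list(
      param_spec("lk_mean", 1, function(v, s) dnorm(v, 1, 1, log = TRUE)),
      param_spec("lk_prec", 1, function(v, s)
        dgamma(v, 2, rate = 1, log = TRUE), "log"),
      param_spec("kappa1", 2, hp, "log"),
      param_spec("kappa2", 2, hp, "log"),
      param_spec("clock_rate", 0.5, function(v, s)
        dlnorm(v, 0, 2, log = TRUE), "log")),
    components = list(
      density_component("part1", function(s)
        prune_loglik(tr, pm1, model = build_hky(freqs, s$kappa1),
                     clock_rate = s$clock_rate),
        depends = c("kappa1", "clock_rate")),
      density_component("part2", function(s)
        prune_loglik(tr, pm2, model = build_hky(freqs, s$kappa2),
                     clock_rate = s$clock_rate),
        depends = c("kappa2", "clock_rate"))))
  ks <- list(kernel_scale("kappa1"), kernel_scale("kappa2"),
             kernel_scale("clock_rate"), kernel_walk("lk_mean", sd = 0.5),
             kernel_scale("lk_prec"))
  fit <- run_mcmc(g, ks, 12000, log_every = 10, rng_seed = 18)
  s <- fit$samples[-(1:200), ]
  ## unlinked kappas separate toward their own truths; linked clock is one
  ## column informed by both partitions
  expect_gt(mean(s$kappa2), mean(s$kappa1))
  expect_lt(abs(mean(s$clock_rate) - 0.5), 0.25)
  ## the joint posterior column is the sum of both partition likelihoods
  expect_equal(s$posterior, s$prior + s$likelihood, tolerance = 1e-8)
})

test_that("ESS estimator calibrates against known processes", {
  set.seed(13)
  x <- rnorm(10000)
  expect_gt(ess(x), 8000)
  expect_lt(ess(x), 12000)
  ## AR(1): ESS ~= n (1 - phi) / (1 + phi)
  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), 10000))
  expect_lt(abs(ess(ar) - 10000 * (1 - phi) / (1 + phi)) /
              (10000 * (1 - phi) / (1 + phi)), 0.3)
  z <- ess(rep(1, 10))
  expect_equal(as.numeric(z), 10)
  expect_true(attr(z, "zero_variance"))
  expect_error(ess(1:5), "at least 10")
})
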