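conjugate_setup <- function(seed = 4, n = 10) {
  set.seed(seed)
  y <- rnorm(n, 0.7, 1)
  list(y = y, graph = normal_mean_graph(y, 1, 0, 1),
       kernels = list(kernel_walk("mu", sd = 0.8)),
       truth = conjugate_logml(y, 1, 0, 1))
}

test_that("beta ladders are decreasing, span [1, 0] and front-load the prior", {
  b <- beta_ladder(50)
  expect_equal(b[1], 1)
  expect_equal(b[50], 0)
  expect_true(all(diff(b) < 0))
  ## Beta(0.3, 1) quantiles concentrate rungs near beta = 0
  expect_gt(sum(b < 0.1), sum(b > 0.9))
  expect_error(beta_ladder(1), "R >= 2")
})

test_that("power-posterior rungs have the documented limiting targets", {
  cs <- conjugate_setup()
  lad <- run_power_posterior(cs$graph, cs$kernels, c(1, 0.5, 0),
                             n_samples = 600, burnin = 200, rng_seed = 1)
  ## beta = 0 rung samples the prior, so its likelihood draws are far more
  ## dispersed (prior-predictive) than the posterior rung's
  expect_gt(var(lad$loglik[, 3]), var(lad$loglik[, 1]))
  ## seeded reproducibility end to end
  lad2 <- run_power_posterior(cs$graph, cs$kernels, c(1, 0.5, 0),
                              n_samples = 600, burnin = 200, rng_seed = 1)
  expect_identical(lad$loglik, lad2$loglik)
})

test_that("PS, SS and GSS all hit the closed-form conjugate marginal", {
  cs <- conjugate_setup()
  lad <- run_power_posterior(cs$graph, cs$kernels, beta_ladder(50),
                             n_samples = 1000, burnin = 200, rng_seed = 2)
  ps <- path_sampling_estimate(lad)
  ss <- stepping_stone_estimate(lad)
  pilot <- run_mcmc(cs$graph, cs$kernels, 3000, log_every = 2, rng_seed = 3)
  wd <- fit_working_distribution(pilot, cs$graph)
  gs <- gss_estimate(cs$graph, cs$kernels, wd, beta_ladder(10),
                     n_samples = 1000, burnin = 200, rng_seed = 4)
  expect_lt(abs(ps - cs$truth), 0.1)
  expect_lt(abs(ss - cs$truth), 0.1)
  expect_lt(abs(gs$logml - cs$truth), 0.1)   # GSS: 10 rungs suffice
  expect_lt(abs(ps - ss), 0.2)
  expect_lt(abs(ps - gs$logml), 0.2)
  expect_lt(abs(ss - gs$logml), 0.2)
})

test_that("degenerate ladders behave as documented", {
  cs <- conjugate_setup()
  ## equal log-likelihood at every rung: PS returns that constant
  lad <- list(betas = beta_ladder(5),
              loglik = matrix(-3.2, 100, 5), logratio = NULL,
              kind = "power")
  class(lad) <- "power_posterior_ladder"
  expect_equal(path_sampling_estimate(lad), -3.2)
  expect_equal(stepping_stone_estimate(lad), -3.2)
  expect_error(path_sampling_estimate(list(betas = 1, loglik = cbind(1))),
               "2 rungs")
  ## single stone (beta = 1, 0) reduces to importance sampling from the prior
  set.seed(5)
  lad1 <- run_power_posterior(cs$graph, cs$kernels, c(1, 0),
                              n_samples = 4000, burnin = 300, rng_seed = 6)
  ss1 <- stepping_stone_estimate(lad1)
  mu_prior <- rnorm(200000, 0, 1)
  ll <- vapply(mu_prior, function(m)
    sum(dnorm(cs$y, m, 1, log = TRUE)), numeric(1))
  is_est <- max(ll) + log(mean(exp(ll - max(ll))))
  expect_lt(abs(ss1 - is_est), 0.25)
  ## halving the rung count degrades smoothly, never to NaN
  lad25 <- run_power_posterior(cs$graph, cs$kernels, beta_ladder(25),
                               n_samples = 400, burnin = 150, rng_seed = 7)
  expect_true(is.finite(path_sampling_estimate(lad25)))
  expect_true(is.finite(stepping_stone_estimate(lad25)))
})

test_that("Beta-spaced rungs beat uniform spacing on the conjugate battery", {
  ## sharper likelihood (more data, shifted mean) so the prior-posterior
  ## gap that rung placement must bridge is substantial
  set.seed(4)
  y <- rnorm(40, 2, 1)
  g <- normal_mean_graph(y, 1, 0, 1)
  ks <- list(kernel_walk("mu", sd = 0.5))
  truth <- conjugate_logml(y, 1, 0, 1)
  err_beta <- err_unif <- numeric(20)
  for (i in 1:20) {
    lb <- run_power_posterior(g, ks, beta_ladder(12),
                              n_samples = 300, burnin = 100, rng_seed = 100 + i)
    lu <- run_power_posterior(g, ks, seq(1, 0, length.out = 12),
                              n_samples = 300, burnin = 100, rng_seed = 200 + i)
    err_beta[i] <- abs(stepping_stone_estimate(lb) - truth)
    err_unif[i] <- abs(stepping_stone_estimate(lu) - truth)
  }
  expect_lt(median(err_beta), median(err_unif))
})

test_that("working distributions are moment-matched, inflated and safe", {
  cs <- conjugate_setup()
  pilot <- run_mcmc(cs$graph, cs$kernels, 6000, log_every = 2, rng_seed = 8)
  wd <- fit_working_distribution(pilot, cs$graph, inflate = 2)
  ## posterior is exactly normal: N(n ybar/(n+1), 1/(n+1))
  n <- length(cs$y)
  expect_lt(abs(wd$mean["mu"] - n * mean(cs$y) / (n + 1)), 0.05)
  expect_lt(abs(wd$sd["mu"] - 2 * sqrt(1 / (n + 1))), 0.06)
  ## deterministic given the trace
  expect_identical(wd, fit_working_distribution(pilot, cs$graph, inflate = 2))
  ## every posterior sample has a finite, non-extreme reference density
  dens <- vapply(pilot$samples$mu, function(m)
    working_log_density(wd, list(mu = m)), numeric(1))
  expect_true(all(is.finite(dens)))
  expect_gt(mean(dens > max(dens) - 20), 0.99)
  ## zero-variance parameter triggers the point-mass warning path
  fake <- pilot
  fake$samples$mu <- rep(1, nrow(fake$samples))
  expect_warning(fit_working_distribution(fake, cs$graph), "point mass")
})

test_that("an ideal working distribution makes a two-rung GSS accurate", {
  cs <- conjugate_setup()
  n <- length(cs$y)
  wd <- structure(list(params = "mu", transforms = "none",
                       mean = c(mu = n * mean(cs$y) / (n + 1)),
                       sd = c(mu = sqrt(1 / (n + 1))), inflate = 1),
                  class = "working_distribution")
  gs <- gss_estimate(cs$graph, cs$kernels, wd, c(1, 0),
                     n_samples = 2000, burnin = 200, rng_seed = 9)
  expect_lt(abs(gs$logml - cs$truth), 0.02)
})

test_that("model selection by log-BF separates active from null effects", {
  ## nested normal-mean models: M0 fixes mu = 0, M1 samples mu
  logml_m0 <- function(y) sum(dnorm(y, 0, 1, log = TRUE))
  wins_null <- wins_active <- 0
  reps <- 10
  for (i in seq_len(reps)) {
    set.seed(300 + i)
    y_null <- rnorm(12, 0, 1)       # extra parameter is superfluous
    y_act <- rnorm(12, 1.5, 1)      # extra parameter is real
    for (case in c("null", "active")) {
      y <- if (case == "null") y_null else y_act
      g <- normal_mean_graph(y, 1, 0, 1)
      lad <- run_power_posterior(g, list(kernel_walk("mu", sd = 0.8)),
                                 beta_ladder(12), n_samples = 300,
                                 burnin = 100, rng_seed = 400 + i)
      bf <- stepping_stone_estimate(lad) - logml_m0(y)
      if (case == "null" && bf < 1) wins_null <- wins_null + 1
      if (case == "active" && bf > 3) wins_active <- wins_active + 1
    }
  }
  expect_gte(wins_null, 9)
  expect_gte(wins_active, 9)
})
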