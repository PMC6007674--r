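## ------------------------------------------------------------------
## Reversible (and general) continuous-time Markov substitution models.
## The same machinery serves 4-state nucleotide models and K-state
## discrete-trait models: a normalized generator Q plus an eigensystem
## used for fast transition probabilities and jump/reward integrals.
## ------------------------------------------------------------------

#' Build a CTMC model from a generator
#'
#' Assembles the normalized generator, stationary frequencies and the
#' eigensystem.  Reversible models are decomposed through the symmetric
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))` similarity transform; general
#' (e.g. asymmetric trait GLM) matrices use the plain eigendecomposition
#' with a conditioning check, falling back to scaling-and-squaring.
#'
#' @param rates K x K matrix of non-negative off-diagonal rates (diagonal
#'   ignored).
#' @param freqs stationary frequencies if known (reversible construction);
#'   if `NULL` they are solved from `pi Q = 0`.
#' @param normalize rescale so that `-sum(pi_i Q_ii) = 1` (one expected
#'   event per unit time).
#' @param reversible declare the model reversible (detailed balance is
#'   verified).
#' @return a `ctmc_model`: list with `K`, `Q`, `freqs`, `eigen`
#'   (`values`, `vectors`, `inv`), `reversible`, `defective`.
#' @export
ctmc_model <- function(rates, freqs = NULL, normalize = TRUE,
                       reversible = !is.null(freqs)) {
  force(reversible)
  K <- nrow(rates)
  stopifnot(ncol(rates) == K, K >= 2)
  Q <- rates
  diag(Q) <- 0
  if (any(Q < 0)) stop("off-diagonal rates must be non-negative")
  diag(Q) <- -rowSums(Q)
  eig <- NULL
  if (is.null(freqs)) {
    ## one general eigendecomposition serves both the stationary
    ## distribution (left null eigenvector = matching row of V^-1) and
    ## the transition probabilities
    es <- eigen(Q, symmetric = FALSE)
    Vinv <- tryCatch(solve(es$vectors), error = function(e) NULL)
    if (is.null(Vinv) ||
        max(Mod(es$vectors %*% Vinv - diag(K))) > 1e-8) {
      eig <- list(values = es$values, vectors = es$vectors, inv = Vinv,
                  defective = TRUE)
      ns <- eigen(t(Q), symmetric = FALSE)
      v <- Re(ns$vectors[, which.min(abs(ns$values))])
    } else {
      eig <- list(values = es$values, vectors = es$vectors, inv = Vinv,
                  defective = FALSE)
      v <- Re(Vinv[which.min(abs(es$values)), ])
    }
    v <- v * sign(sum(v))
    freqs <- v / sum(v)
  }
  if (any(freqs <= 0)) stop("stationary frequencies must be strictly positive")
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  if (normalize) {
    mu <- -sum(freqs * diag(Q))
    Q <- Q / mu
    if (!is.null(eig)) eig$values <- eig$values / mu
  }
  if (reversible) {
    flux <- freqs * Q
    if (max(abs(flux - t(flux))) > 1e-8 * max(abs(Q)))
      stop("rate matrix does not satisfy detailed balance for given freqs")
  }
  if (is.null(eig)) eig <- decompose_generator(Q, freqs, reversible)
  Amat <- NULL
  if (!eig$defective && !is.null(eig$inv)) {
    Amat <- matrix(if (is.complex(eig$values) || is.complex(eig$vectors))
      0 + 0i else 0, K * K, K)
    for (k in seq_len(K))
      Amat[, k] <- as.vector(outer(eig$vectors[, k], eig$inv[k, ]))
  }
  structure(list(K = K, Q = Q, freqs = as.numeric(freqs), eigen = eig,
                 reversible = reversible, defective = eig$defective,
                 Amat = Amat),
            class = "ctmc_model")
}

decompose_generator <- function(Q, freqs, reversible) {
  K <- nrow(Q)
  if (reversible) {
    sq <- sqrt(freqs)
    S <- diag(sq) %*% Q %*% diag(1 / sq)
    S <- (S + t(S)) / 2
    es <- eigen(S, symmetric = TRUE)
    V <- diag(1 / sq) %*% es$vectors
    Vinv <- t(es$vectors) %*% diag(sq)
    list(values = es$values, vectors = V, inv = Vinv, defective = FALSE)
  } else {
    es <- eigen(Q, symmetric = FALSE)
    Vinv <- tryCatch(solve(es$vectors), error = function(e) NULL)
    defective <- is.null(Vinv) ||
      max(Mod(es$vectors %*% Vinv - diag(nrow(Q)))) > 1e-8
    if (defective)
      list(values = es$values, vectors = es$vectors, inv = Vinv,
           defective = TRUE)
    else
      list(values = es$values, vectors = es$vectors, inv = Vinv,
           defective = FALSE)
  }
}

#' HKY substitution model
#'
#' Off-diagonal rate to state j is proportional to `kappa * pi_j` for
#' transitions (A<->G, C<->T) and `pi_j` for transversions.  With
#' `kappa = 1` and equal frequencies this reduces to Jukes-Cantor.
#'
#' @param freqs stationary frequencies in order A, C, G, T.
#' @param kappa transition/transversion rate ratio, positive.
#' @param normalize see [ctmc_model()].
#' @return a `ctmc_model` with 4 states.
#' @export
build_hky <- function(freqs, kappa, normalize = TRUE) {
  stopifnot(length(freqs) == 4)
  if (any(freqs <= 0)) stop("frequencies must be strictly positive")
  if (kappa <= 0) stop("kappa must be positive")
  freqs <- freqs / sum(freqs)
  ## states A, C, G, T; transitions are A-G and C-T
  R <- matrix(1, 4, 4)
  R[1, 3] <- R[3, 1] <- kappa
  R[2, 4] <- R[4, 2] <- kappa
  rates <- R * rep(freqs, each = 4)
  m <- ctmc_model(rates, freqs = freqs, normalize = normalize,
                  reversible = TRUE)
  m$name <- "HKY"
  m$kappa <- kappa
  m
}

#' GTR substitution model
#'
#' @param freqs stationary frequencies (A, C, G, T).
#' @param exchange six exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param normalize see [ctmc_model()].
#' @return a `ctmc_model`.
#' @export
build_gtr <- function(freqs, exchange, normalize = TRUE) {
  stopifnot(length(freqs) == 4, length(exchange) == 6)
  if (any(freqs <= 0) || any(exchange <= 0))
    stop("frequencies and exchangeabilities must be positive")
  freqs <- freqs / sum(freqs)
  R <- matrix(0, 4, 4)
  R[1, 2] <- exchange[1]; R[1, 3] <- exchange[2]; R[1, 4] <- exchange[3]
  R[2, 3] <- exchange[4]; R[2, 4] <- exchange[5]; R[3, 4] <- exchange[6]
  R <- R + t(R)
  rates <- R * rep(freqs, each = 4)
  m <- ctmc_model(rates, freqs = freqs, normalize = normalize,
                  reversible = TRUE)
  m$name <- "GTR"
  m
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `ctmc_model`.
#' @param t non-negative elapsed time (branch duration in expected-event
#'   units after clock scaling).
#' @return K x K stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  if (t < 0) stop("elapsed time must be non-negative")
  if (model$defective)
    return(as.matrix(Matrix::expm(model$Q * t)))
  e <- model$eigen
  P <- e$vectors %*% (exp(e$values * t) * e$inv)
  P <- Re(P)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probabilities for many branch durations at once
#'
#' Vectorized form used by the pruning engine: entries of P(t) are
#' `sum_k A_k[i,j] exp(lambda_k t)` with spectral projectors `A_k`.
#'
#' @param model a `ctmc_model`.
#' @param ts numeric vector of non-negative durations.
#' @return numeric array `K x K x length(ts)`.
#' @export
transition_prob_array <- function(model, ts) {
  if (any(ts < 0)) stop("elapsed times must be non-negative")
  K <- model$K
  if (model$defective) {
    out <- array(0, c(K, K, length(ts)))
    for (i in seq_along(ts))
      out[, , i] <- as.matrix(Matrix::expm(model$Q * ts[i]))
    return(out)
  }
  e <- model$eigen
  cplx <- is.complex(e$values) || is.complex(e$vectors)
  ## Amat[(i,j), k] = V[i,k] * Vinv[k,j] (spectral projectors, flattened)
  Amat <- if (is.null(model$Amat)) {
    A <- matrix(if (cplx) 0 + 0i else 0, K * K, K)
    for (k in seq_len(K))
      A[, k] <- as.vector(outer(e$vectors[, k], e$inv[k, ]))
    A
  } else model$Amat
  E <- exp(outer(e$values, ts))          # K x nt
  P <- Amat %*% E                        # (K*K) x nt
  if (cplx) P <- Re(P)
  P[P < 0] <- 0
  out <- array(P, c(K, K, length(ts)))
  rs <- colSums(aperm(out, c(2L, 1L, 3L)))   # K x nt row sums
  for (j in seq_len(K)) out[, j, ] <- out[, j, ] / rs
  out
}

## -- discrete gamma rate heterogeneity -----------------------------

#' Discrete-gamma site-rate model
#'
#' `k` equal-probability categories; the rate of category c is the mean of
#' a gamma(shape = alpha, rate = alpha) distribution over its quantile
#' bin, so the category rates always average exactly one.
#'
#' @param alpha gamma shape, positive.
#' @param k number of categories, >= 1.
#' @return a `site_rate_model`: list with `k`, `alpha`, `rates`, `probs`.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (k < 1) stop("need at least one rate category")
  if (alpha <= 0) stop("gamma shape must be positive")
  k <- as.integer(k)
  if (k == 1L) {
    rates <- 1
  } else {
    cuts <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
    ## mean of X over a bin: uses the shape+1 incomplete-gamma identity
    up <- pgamma(c(cuts, Inf), shape = alpha + 1, rate = alpha)
    lo <- pgamma(c(0, cuts), shape = alpha + 1, rate = alpha)
    rates <- k * (up - lo)
    rates <- rates / mean(rates)   # exact unit mean despite rounding
  }
  structure(list(k = k, alpha = alpha, rates = rates, probs = rep(1 / k, k)),
            class = "site_rate_model")
}

#' Single-rate site model (no heterogeneity)
#' @export
uniform_rate_model <- function() {
  structure(list(k = 1L, alpha = Inf, rates = 1, probs = 1),
            class = "site_rate_model")
}
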