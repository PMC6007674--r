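## ------------------------------------------------------------------
## Coalescent tree priors: constant effective population size and the
## GMRF skygrid (piecewise-constant log-Ne on a fixed height grid) with
## an optional covariate design entering as a mean shift of the field.
## ------------------------------------------------------------------

#' Constant-size demographic model
#' @param Ne effective population size (> 0), in tree-time units.
#' @return a `demographic_model`.
#' @export
constant_demography <- function(Ne) {
  if (Ne <= 0) stop("Ne must be positive")
  structure(list(kind = "constant", Ne = Ne), class = "demographic_model")
}

#' Skygrid demographic model
#'
#' Piecewise-constant log effective population size on a fixed grid of
#' heights: `gamma[m]` applies on `[cuts[m-1], cuts[m])` (with
#' `cuts[0] = 0`) and the last value extends to infinity.
#'
#' @param cuts strictly increasing positive grid cut points
#'   `t_1 < ... < t_{M-1}` (the M-th cell is unbounded).
#' @param gamma log-Ne vector of length `M = length(cuts) + 1`.
#' @param tau GMRF precision (> 0) for the smoothing prior.
#' @param Z optional `M x P` covariate design (time-varying predictors of
#'   log-Ne).
#' @param beta_cov covariate coefficients, length `P`.
#' @return a `demographic_model`.
#' @export
skygrid_demography <- function(cuts, gamma, tau = 1, Z = NULL,
                               beta_cov = NULL) {
  if (length(cuts) && (any(diff(cuts) <= 0) || any(cuts <= 0)))
    stop("grid cut points must be strictly increasing and positive")
  if (length(gamma) != length(cuts) + 1L)
    stop("gamma must have one more entry than the cut points")
  if (any(!is.finite(gamma))) stop("gamma must be finite")
  if (tau <= 0) stop("GMRF precision tau must be positive")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(gamma)) stop("Z must have M rows")
    if (is.null(beta_cov) || length(beta_cov) != ncol(Z))
      stop("beta_cov must match the covariate columns")
  }
  structure(list(kind = "skygrid", cuts = as.numeric(cuts),
                 gamma = as.numeric(gamma), tau = tau, Z = Z,
                 beta_cov = beta_cov),
            class = "demographic_model")
}

#' Default skygrid grid for a starting tree
#'
#' Equal-width grid from zero to the root height with `M` cells.
#' @param tree a `timetree`.
#' @param M number of grid cells.
#' @return numeric cut points of length `M - 1`.
#' @export
default_skygrid_cuts <- function(tree, M = 10) {
  h <- tree$heights[tree$root]
  seq(0, h, length.out = M + 1L)[2:M]
}

#' Coalescent and sampling intervals of a time tree
#'
#' Going back in time the active-lineage count rises by one at each tip
#' and falls by one at each coalescence, ending at one above the root.
#'
#' @param tree a `timetree`.
#' @return an `interval_set`: data.frame with columns `start`, `end`
#'   (heights), `k` (lineages active on the interval), plus attribute
#'   `coal_heights`.
#' @export
extract_intervals <- function(tree) {
  ntip <- tree$ntip
  ev <- data.frame(h = tree$heights,
                   d = c(rep(1L, ntip), rep(-1L, tree$nnode - ntip)))
  ev <- ev[order(ev$h, -ev$d), ]   # at ties, sampling before coalescence
  k <- cumsum(ev$d)
  starts <- ev$h[-nrow(ev)]
  ends <- ev$h[-1L]
  out <- data.frame(start = starts, end = ends, k = head(k, -1L))
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$k < 1L)) stop("invalid lineage count; malformed tree")
  attr(out, "coal_heights") <-
    sort(tree$heights[(ntip + 1L):tree$nnode])
  class(out) <- c("interval_set", "data.frame")
  out
}

ne_at <- function(dm, h) {
  if (dm$kind == "constant") return(rep(dm$Ne, length(h)))
  cell <- findInterval(h, dm$cuts) + 1L
  exp(dm$gamma[cell])
}

#' Coalescent log-likelihood of a time tree
#'
#' `sum over intervals of -k(k-1)/(2 Ne(t)) dt  -  sum over coalescent
#' events of log Ne(t_event)`, with `Ne(t)` piecewise constant for the
#' skygrid.  Grid cells are integrated exactly by splitting coalescent
#' intervals at the cut points.
#'
#' @param tree a `timetree`.
#' @param dm a `demographic_model`.
#' @return log-density of the tree under the coalescent.
#' @export
coalescent_loglik <- function(tree, dm) {
  if (dm$kind == "constant" && dm$Ne <= 0) stop("Ne must be positive")
  nnode <- tree$nnode; ntip <- tree$ntip
  h <- tree$heights
  d <- c(rep(1L, ntip), rep(-1L, nnode - ntip))
  o <- order(h, -d)                 # at ties, sampling before coalescence
  hs <- h[o]; ds <- d[o]
  k <- cumsum(ds)[-nnode]
  a <- hs[-nnode]; b <- hs[-1L]
  rate <- k * (k - 1) / 2
  if (dm$kind == "constant")
    return(-sum(rate * (b - a)) / dm$Ne - (ntip - 1) * log(dm$Ne))
  ## skygrid: F(t) = int_0^t 1/Ne(s) ds is piecewise linear in t
  cuts <- dm$cuts
  inv_ne <- exp(-dm$gamma)
  Fcum <- c(0, cumsum(diff(c(0, cuts)) * inv_ne[seq_along(cuts)]))
  lower <- c(0, cuts)
  Fof <- function(t) {
    j <- findInterval(t, cuts) + 1L
    Fcum[j] + (t - lower[j]) * inv_ne[j]
  }
  ll <- -sum(rate * (Fof(b) - Fof(a)))
  ch <- hs[ds == -1L]
  ll - sum(dm$gamma[findInterval(ch, cuts) + 1L])
}

#' First-order random-walk GMRF log-prior on the skygrid field
#'
#' Covariates enter as a mean shift: the prior penalizes successive
#' differences of the residuals `w = gamma - Z beta_cov`.  The density is
#' the intrinsic (improper-in-level) GMRF
#' `((M-1)/2) log(tau/2pi) - (tau/2) sum (w_m - w_{m-1})^2`; the overall
#' level is identified by the coalescent likelihood.
#'
#' @param gamma log-Ne vector, length `M >= 2`.
#' @param tau precision (> 0).
#' @param Z optional `M x P` design.
#' @param beta_cov coefficients, length `P`.
#' @return log-prior density.
#' @export
gmrf_log_prior <- function(gamma, tau, Z = NULL, beta_cov = NULL) {
  if (tau <= 0) stop("tau must be positive")
  M <- length(gamma)
  if (M < 2L) stop("GMRF needs at least two cells")
  w <- gamma
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != M || length(beta_cov) != ncol(Z))
      stop("covariate dimensions do not match gamma")
    w <- gamma - as.vector(Z %*% beta_cov)
  }
  ((M - 1) / 2) * log(tau / (2 * pi)) - (tau / 2) * sum(diff(w)^2)
}
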