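## ------------------------------------------------------------------
## Pruning likelihood of an alignment partition (or a discrete trait
## column) given a time tree, a CTMC model, a site-rate model and a
## strict-clock rate.  The peel itself runs in compiled code; this file
## assembles tip partials and per-branch transition matrices.
## ------------------------------------------------------------------

iupac_partials <- local({
  tab <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
    `?` = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
  )
  states <- c("A", "C", "G", "T")
  m <- matrix(0, length(tab), 4, dimnames = list(names(tab), states))
  for (i in seq_along(tab)) m[i, tab[[i]]] <- 1
  m
})

#' Tip partial likelihoods for nucleotide patterns
#'
#' Ambiguity codes N, -, ? give partial likelihood 1 for every state;
#' two/three-state IUPAC codes set the matching entries to 1.
#'
#' @param patterns character matrix, taxa x patterns.
#' @return numeric array `4 x npat x ntaxa`.
#' @export
nucleotide_tip_partials <- function(patterns) {
  ntaxa <- nrow(patterns)
  npat <- ncol(patterns)
  chars <- toupper(patterns)
  bad <- setdiff(unique(as.vector(chars)), rownames(iupac_partials))
  if (length(bad))
    stop("unknown nucleotide code(s): ", paste(bad, collapse = ", "))
  out <- array(0, c(4L, npat, ntaxa))
  for (t in seq_len(ntaxa))
    out[, , t] <- t(iupac_partials[chars[t, ], , drop = FALSE])
  dimnames(out) <- list(NULL, NULL, rownames(patterns))
  out
}

#' Tip partial likelihoods for a discrete trait
#'
#' @param states named character vector taxon -> state label; `"?"` or
#'   `NA` marks a missing (fully ambiguous) tip.
#' @param levels the K state labels in model order.
#' @return numeric array `K x 1 x ntaxa`.
#' @export
trait_tip_partials <- function(states, levels) {
  K <- length(levels)
  ntaxa <- length(states)
  out <- array(0, c(K, 1L, ntaxa))
  for (t in seq_len(ntaxa)) {
    s <- states[t]
    if (is.na(s) || s == "?") {
      out[, 1L, t] <- 1
    } else {
      i <- match(s, levels)
      if (is.na(i)) stop("unknown trait state '", s, "' for taxon ",
                         names(states)[t])
      out[i, 1L, t] <- 1
    }
  }
  dimnames(out) <- list(levels, NULL, names(states))
  out
}

#' Assemble a partition model
#'
#' Bundles the site patterns (with precomputed tip partials), the
#' substitution model, the site-rate model and the strict-clock rate.
#' Partitions that share a link group must share the identical parameter
#' object; linking is handled at the model-graph level.
#'
#' @param patterns a `patternset` from [compress_patterns()], or a list
#'   with `patterns`, `weights`, `taxa` for trait data.
#' @param model a `ctmc_model`.
#' @param site_rates a `site_rate_model` (default: single rate).
#' @param clock_rate strict-clock rate, events per unit tree time.
#' @param tip_partials optional precomputed array `K x npat x ntaxa`
#'   (taxon order = `patterns$taxa`); built from the characters when
#'   omitted (nucleotide models only).
#' @return a `partition_model`.
#' @export
partition_model <- function(patterns, model, site_rates = uniform_rate_model(),
                            clock_rate = 1, tip_partials = NULL) {
  if (clock_rate <= 0) stop("clock rate must be positive")
  if (is.null(tip_partials)) {
    if (model$K != 4L)
      stop("automatic tip partials only for 4-state models; supply tip_partials")
    tip_partials <- nucleotide_tip_partials(patterns$patterns)
  }
  structure(list(patterns = patterns, model = model, site_rates = site_rates,
                 clock_rate = clock_rate, tip_partials = tip_partials,
                 cache = new.env(parent = emptyenv())),
            class = "partition_model")
}

#' Pruning log-likelihood
#'
#' Computes `sum_p w_p log sum_i pi_i L_root,i(p)` by postorder peeling,
#' with per-branch transition matrices `P(mu r_c (h_parent - h_child))`
#' and equal-probability rate-category averaging at the site level.
#' Per-node rescaling keeps the computation finite for large trees.
#'
#' @param tree a `timetree`.
#' @param pm a `partition_model`.
#' @param model,clock_rate optional overrides of the partition's
#'   substitution model and clock rate (used by MCMC kernels so tip
#'   partials are not rebuilt every step).
#' @return the log-likelihood (finite for valid inputs).
#' @export
prune_loglik <- function(tree, pm, model = pm$model,
                         clock_rate = pm$clock_rate) {
  taxa <- pm$patterns$taxa
  key <- paste(tree$tip_label, collapse = "\r")
  cached <- !is.null(pm$cache) && identical(pm$cache$key, key)
  if (cached) {
    tipp_flat <- pm$cache$tipp_flat
  } else {
    ord <- match(tree$tip_label, taxa)
    if (anyNA(ord)) stop("tree tips missing from pattern taxa: ",
                         paste(tree$tip_label[is.na(ord)], collapse = ", "))
    ## flatten to tip-major: [(t*npat + p)*K + i]
    tipp_flat <- as.vector(pm$tip_partials[, , ord, drop = FALSE])
    if (!is.null(pm$cache)) {
      pm$cache$key <- key
      pm$cache$tipp_flat <- tipp_flat
    }
  }
  K <- model$K
  npat <- length(pm$patterns$weights)
  ncat <- pm$site_rates$k
  nnode <- tree$nnode
  nonroot <- setdiff(seq_len(nnode), tree$root)
  bl <- branch_length(tree, nonroot)
  ## branch "time" = mu * r_c * delta-height for every (node, category)
  ts <- as.vector(outer(bl * clock_rate, pm$site_rates$rates))
  idx <- as.vector(outer(nonroot, (seq_len(ncat) - 1L) * nnode, `+`))
  if (!model$defective && !is.null(model$Amat)) {
    ## fast path: transition matrices built inside the compiled peel
    ts_full <- rep(-1, nnode * ncat)
    ts_full[idx] <- ts
    po <- postorder_nodes(tree)
    w <- as.numeric(pm$patterns$weights)
    if (!is.complex(model$Amat))
      return(peel_spectral_cpp(po, tree$children, tree$root, tree$ntip,
                               nnode, K, npat, ncat, model$Amat,
                               model$eigen$values, ts_full, tipp_flat,
                               model$freqs, w, pm$site_rates$probs))
    return(peel_spectral_cplx_cpp(po, tree$children, tree$root, tree$ntip,
                                  nnode, K, npat, ncat, Re(model$Amat),
                                  Im(model$Amat), Re(model$eigen$values),
                                  Im(model$eigen$values), ts_full,
                                  tipp_flat, model$freqs, w,
                                  pm$site_rates$probs))
  }
  Parr <- transition_prob_array(model, ts)
  P <- array(0, c(K, K, nnode * ncat))
  P[, , idx] <- Parr
  peel_loglik_cpp(postorder_nodes(tree), tree$children, tree$root,
                  tree$ntip, nnode, K, npat, ncat,
                  as.vector(P), tipp_flat, model$freqs,
                  as.numeric(pm$patterns$weights), pm$site_rates$probs)
}

#' Reference pruning likelihood in pure R (validation aid)
#'
#' Slow direct implementation used to cross-check the compiled peeler on
#' small problems.
#' @inheritParams prune_loglik
#' @return log-likelihood.
#' @export
prune_loglik_reference <- function(tree, pm, model = pm$model,
                                   clock_rate = pm$clock_rate) {
  taxa <- pm$patterns$taxa
  ord <- match(tree$tip_label, taxa)
  K <- model$K
  npat <- length(pm$patterns$weights)
  total <- 0
  for (p in seq_len(npat)) {
    site <- 0
    for (c in seq_len(pm$site_rates$k)) {
      partial <- matrix(0, tree$nnode, K)
      for (t in seq_len(tree$ntip))
        partial[t, ] <- pm$tip_partials[, p, ord[t]]
      for (v in postorder_nodes(tree)) {
        acc <- rep(1, K)
        for (ch in tree$children[v, ]) {
          t_br <- branch_length(tree, ch) * clock_rate *
            pm$site_rates$rates[c]
          Pm <- transition_probabilities(model, t_br)
          acc <- acc * as.vector(Pm %*% partial[ch, ])
        }
        partial[v, ] <- acc
      }
      site <- site + pm$site_rates$probs[c] *
        sum(model$freqs * partial[tree$root, ])
    }
    total <- total + pm$patterns$weights[p] * log(site)
  }
  total
}
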