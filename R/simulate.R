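## ------------------------------------------------------------------
## Synthetic-data generators: coalescent trees (piecewise-constant Ne,
## serial sampling), sequence alignments, discrete trait histories with
## retained truth, continuous Brownian traits and GLM predictor designs.
## Every generator is seeded and its output satisfies the invariants of
## the consuming module.
## ------------------------------------------------------------------

## waiting time to coalescence from height h with k lineages under a
## piecewise-constant Ne(t): exponential hazard consumed cell by cell
draw_coal_height <- function(h, k, dm) {
  E <- rexp(1)
  rate_f <- k * (k - 1) / 2
  if (dm$kind == "constant")
    return(h + E * dm$Ne / rate_f)
  bounds <- c(dm$cuts[dm$cuts > h], Inf)
  lo <- h
  cell <- findInterval(lo, dm$cuts) + 1L
  for (up in bounds) {
    ne <- exp(dm$gamma[cell])
    lam <- rate_f / ne
    if (is.infinite(up) || E <= lam * (up - lo))
      return(lo + E / lam)
    E <- E - lam * (up - lo)
    lo <- up
    cell <- cell + 1L
  }
  stop("unreachable")
}

#' Simulate a coalescent time tree
#'
#' Standard (serial-sampling) coalescent with piecewise-constant
#' effective population size: going back in time, lineages activate at
#' their tip heights and pairs merge at rate `k(k-1)/(2 Ne(t))`.
#'
#' @param tip_heights numeric tip sampling heights (0 = most recent);
#'   use `rep(0, n)` for contemporaneous sampling.
#' @param dm a `demographic_model` ([constant_demography()] or
#'   [skygrid_demography()]).
#' @param labels tip labels (default `t1..tn`).
#' @param seed optional RNG seed.
#' @return a `timetree`.
#' @export
simulate_coalescent_tree <- function(tip_heights, dm,
                                     labels = paste0("t", seq_along(tip_heights)),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tip_heights)
  stopifnot(n >= 2, min(tip_heights) >= 0)
  tip_heights <- tip_heights - min(tip_heights)
  nnode <- 2L * n - 1L
  parent <- integer(nnode)
  heights <- c(tip_heights, numeric(n - 1L))
  pending <- order(tip_heights)           # tips not yet active
  active <- integer(0)
  h <- 0
  next_internal <- n + 1L
  repeat {
    ## activate tips at or below current height
    while (length(pending) && tip_heights[pending[1L]] <= h) {
      active <- c(active, pending[1L])
      pending <- pending[-1L]
    }
    if (length(active) <= 1L && !length(pending)) break
    if (length(active) >= 2L) {
      hc <- draw_coal_height(h, length(active), dm)
      if (length(pending) && tip_heights[pending[1L]] < hc) {
        h <- tip_heights[pending[1L]]
        next
      }
      pair <- sample(length(active), 2L)
      v <- next_internal
      heights[v] <- hc
      parent[active[pair]] <- v
      active <- c(active[-pair], v)
      next_internal <- next_internal + 1L
      h <- hc
    } else {
      h <- tip_heights[pending[1L]]
    }
  }
  timetree(parent, heights, labels)
}

#' Simulate a nucleotide alignment down a time tree
#'
#' The root sequence is drawn from the stationary frequencies; states
#' then evolve along each branch with transition probabilities
#' `P(mu r_c dt)` where `r_c` is the site's rate category.
#'
#' @param tree a `timetree`.
#' @param model a `ctmc_model` (4 states).
#' @param site_rates a `site_rate_model`.
#' @param clock_rate strict-clock rate (substitutions per site per unit
#'   tree time).
#' @param n_sites number of alignment columns.
#' @param seed optional RNG seed.
#' @return character matrix alignment (tips x sites).
#' @export
simulate_sequences <- function(tree, model, site_rates = uniform_rate_model(),
                               clock_rate, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  letters4 <- c("A", "C", "G", "T")
  cat_of_site <- sample.int(site_rates$k, n_sites, replace = TRUE,
                            prob = site_rates$probs)
  states <- matrix(0L, tree$nnode, n_sites)
  states[tree$root, ] <- sample.int(K, n_sites, replace = TRUE,
                                    prob = model$freqs)
  for (v in rev(postorder_nodes(tree))) {
    for (ch in tree$children[v, ]) {
      dt <- branch_length(tree, ch) * clock_rate
      for (c in seq_len(site_rates$k)) {
        sel <- which(cat_of_site == c)
        if (!length(sel)) next
        P <- transition_probabilities(model, dt * site_rates$rates[c])
        ps <- states[v, sel]
        for (i in seq_len(K)) {
          here <- sel[ps == i]
          if (length(here))
            states[ch, here] <- sample.int(K, length(here), replace = TRUE,
                                           prob = P[i, ])
        }
      }
    }
  }
  aln <- matrix(letters4[states[seq_len(tree$ntip), ]], tree$ntip, n_sites)
  rownames(aln) <- tree$tip_label
  aln
}

#' Simulate a discrete-trait history down a tree
#'
#' Forward simulation of the trait CTMC with the full realization
#' retained, so jump counts and rewards have known truth.
#'
#' @param tree a `timetree`.
#' @param model a `ctmc_model` over trait states.
#' @param clock_rate trait clock rate.
#' @param levels optional state labels for the returned tip states.
#' @param seed optional RNG seed.
#' @return list with `tip_states` (named vector), `node_states`,
#'   `events` (per-branch realization as in [stochastic_map()]),
#'   `n_jumps`.
#' @export
simulate_discrete_trait <- function(tree, model, clock_rate = 1,
                                    levels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  Q <- model$Q
  node_states <- integer(tree$nnode)
  node_states[tree$root] <- sample.int(K, 1L, prob = model$freqs)
  events <- vector("list", tree$nnode)
  njump <- 0L
  for (v in rev(postorder_nodes(tree))) {
    for (ch in tree$children[v, ]) {
      t_br <- branch_length(tree, ch) * clock_rate
      s <- node_states[v]; time <- 0
      ev <- list()
      repeat {
        rate <- -Q[s, s]
        if (rate <= 0) break
        time <- time + rexp(1, rate)
        if (time >= t_br) break
        j <- sample.int(K, 1L, prob = Q[s, ] * (seq_len(K) != s))
        ev[[length(ev) + 1L]] <- c(time, s, j)
        s <- j
      }
      path <- if (length(ev)) do.call(rbind, ev) else matrix(numeric(0), 0, 3)
      colnames(path) <- c("time", "from", "to")
      events[[ch]] <- path
      node_states[ch] <- s
      njump <- njump + nrow(path)
    }
  }
  tips <- node_states[seq_len(tree$ntip)]
  tip_states <- if (is.null(levels)) tips else levels[tips]
  names(tip_states) <- tree$tip_label
  list(tip_states = tip_states, node_states = node_states,
       events = events, n_jumps = njump)
}

#' Simulate multivariate Brownian tip traits
#'
#' Recursive normal increments with per-branch variance
#' `dt * Sigma`.
#'
#' @param tree a `timetree`.
#' @param bm a `brownian_model` (finite root handling: the root state is
#'   `root_mean` plus, if `root_var > 0` and finite, a draw from
#'   `N(0, root_var * Sigma)`; the improper flat root starts at
#'   `root_mean`).
#' @param seed optional RNG seed.
#' @return numeric matrix, tips x d, rownames = tip labels.
#' @export
simulate_continuous_trait <- function(tree, bm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- bm$d
  L <- chol(bm$Sigma)
  X <- matrix(0, tree$nnode, d)
  root_state <- bm$root_mean
  if (is.finite(bm$root_var) && bm$root_var > 0)
    root_state <- root_state + sqrt(bm$root_var) * as.vector(t(L) %*% rnorm(d))
  X[tree$root, ] <- root_state
  for (v in rev(postorder_nodes(tree))) {
    for (ch in tree$children[v, ]) {
      dt <- branch_length(tree, ch)
      X[ch, ] <- X[v, ] + sqrt(dt) * as.vector(t(L) %*% rnorm(d))
    }
  }
  out <- X[seq_len(tree$ntip), , drop = FALSE]
  rownames(out) <- tree$tip_label
  out
}

#' Generate a random standardized GLM predictor design
#'
#' @param K number of trait states.
#' @param P number of predictors.
#' @param seed optional RNG seed.
#' @return standardized `K(K-1) x P` matrix in [ordered_pairs()] order.
#' @export
simulate_glm_design <- function(K, P, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(K * (K - 1L) * P), ncol = P)
  colnames(X) <- paste0("pred", seq_len(P))
  standardize_design(X)
}

#' Write simulation outputs with their truth files
#'
#' Writes the alignment (FASTA), tree (Newick), trait table, predictor
#' design and a tab-delimited truth file recording every generator
#' parameter and the seed, so downstream checks never re-derive truth.
#'
#' @param dir output directory (created if needed).
#' @param tree,aln,traits,design optional components to write.
#' @param truth named list of true parameter values.
#' @param seed the seed used, recorded in the truth file.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, tree = NULL, aln = NULL, traits = NULL,
                             design = NULL, truth = list(), seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(tree))
    writeLines(write_newick(tree), file.path(dir, "tree.nwk"))
  if (!is.null(aln))
    write_fasta_alignment(aln, file.path(dir, "alignment.fasta"))
  if (!is.null(traits)) {
    df <- data.frame(taxon = names(traits), state = unname(traits))
    write.table(df, file.path(dir, "traits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(design)) {
    write.table(as.data.frame(design), file.path(dir, "predictors.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tv <- c(list(seed = seed), truth)
  df <- data.frame(parameter = names(tv),
                   value = vapply(tv, function(x)
                     paste(format(x, digits = 12), collapse = ","), ""))
  write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
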