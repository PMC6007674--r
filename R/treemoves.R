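## ------------------------------------------------------------------
## Time-tree transition kernels.  Each move returns the proposed tree
## and the exact log Hastings ratio, or NULL when no eligible target
## exists (the caller counts this as a rejection without evaluating the
## posterior).  Correctness of the ratios is validated by prior-only
## sampling tests against direct coalescent simulation.
## ------------------------------------------------------------------

## replace children entry oldc of node v with newc
swap_child <- function(tree, v, oldc, newc) {
  i <- which(tree$children[v, ] == oldc)[1L]
  tree$children[v, i] <- newc
  tree
}

#' Root-height scale move
#'
#' Multiplies the root height by `f = exp(delta (u - 1/2))`; rejected
#' outright if the root would drop below a child.
#'
#' @param tree a `timetree`.
#' @param delta tuning window on the log scale.
#' @return list with `tree`, `loghr`, or `NULL` if invalid.
#' @export
move_root_scale <- function(tree, delta = 0.5) {
  f <- exp(delta * (runif(1) - 0.5))
  r <- tree$root
  h <- tree$heights[r] * f
  ch <- tree$children[r, ]
  if (h <= max(tree$heights[ch])) return(NULL)
  tree$heights[r] <- h
  list(tree = tree, loghr = log(f))
}

#' Uniform internal-node height move
#'
#' Redraws the height of a random non-root internal node uniformly
#' between its highest child and its parent (symmetric, Hastings 0).
#' @param tree a `timetree`.
#' @return list with `tree`, `loghr`.
#' @export
move_uniform_height <- function(tree) {
  internal <- setdiff((tree$ntip + 1L):tree$nnode, tree$root)
  if (!length(internal)) return(NULL)
  v <- internal[sample.int(length(internal), 1L)]
  lo <- max(tree$heights[tree$children[v, ]])
  hi <- tree$heights[tree$parent[v]]
  tree$heights[v] <- runif(1, lo, hi)
  list(tree = tree, loghr = 0)
}

#' Narrow exchange
#'
#' Picks uniformly a node with a grandparent and swaps it with its
#' uncle when heights permit.  The reverse move picks the uncle in the
#' proposed tree with the same probability, so the move is symmetric.
#' @param tree a `timetree`.
#' @return list with `tree`, `loghr`, or `NULL`.
#' @export
move_narrow_exchange <- function(tree) {
  has_gp <- which(tree$parent != 0L & tree$parent != tree$root)
  if (!length(has_gp)) return(NULL)
  cc <- has_gp[sample.int(length(has_gp), 1L)]
  p <- tree$parent[cc]
  g <- tree$parent[p]
  u <- setdiff(tree$children[g, ], p)
  if (tree$heights[u] >= tree$heights[p]) return(NULL)
  ## swap uncle u and grandchild cc
  tree <- swap_child(tree, g, u, cc)
  tree <- swap_child(tree, p, cc, u)
  tree$parent[u] <- p
  tree$parent[cc] <- g
  list(tree = tree, loghr = 0)
}

#' Subtree slide
#'
#' Slides the parent of a random non-root node up or down by a normal
#' increment, re-grafting across nodes it passes; the Hastings ratio
#' counts the binary path choices of the reverse move.
#'
#' @param tree a `timetree`.
#' @param sd standard deviation of the slide distance.
#' @return list with `tree`, `loghr`, or `NULL`.
#' @export
move_subtree_slide <- function(tree, sd = 0.5) {
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  i <- nonroot[sample.int(length(nonroot), 1L)]
  p <- tree$parent[i]
  if (p == 0L) return(NULL)
  delta <- rnorm(1, 0, sd)
  newh <- tree$heights[p] + delta
  if (newh <= tree$heights[i]) return(NULL)
  sib <- setdiff(tree$children[p, ], i)
  if (delta > 0) {
    ## climb: cross ancestors of p while newh exceeds them
    k <- 0L
    node <- p
    repeat {
      anc <- tree$parent[node]
      if (anc == 0L || tree$heights[anc] >= newh) break
      node <- anc
      k <- k + 1L
    }
    if (k == 0L) {
      tree$heights[p] <- newh
      return(list(tree = tree, loghr = 0))
    }
    anc <- tree$parent[node]           # attach p on edge (node, anc); node != p
    if (anc == 0L) return(NULL)        # would slide past the root
    g <- tree$parent[p]
    ## detach p: sibling takes p's place under g
    tree <- swap_child(tree, g, p, sib)
    tree$parent[sib] <- g
    ## insert p on edge (node, anc)
    tree <- swap_child(tree, anc, node, p)
    tree$parent[p] <- anc
    tree <- swap_child(tree, p, sib, node)
    tree$parent[node] <- p
    tree$heights[p] <- newh
    return(list(tree = tree, loghr = -k * log(2)))
  } else {
    ## descend along randomly chosen child edges of the sibling subtree
    k <- 0L
    node <- sib
    while (tree$heights[node] > newh) {
      if (node <= tree$ntip) return(NULL)   # slid past a tip
      node <- tree$children[node, sample.int(2L, 1L)]
      k <- k + 1L
    }
    if (k == 0L) {
      tree$heights[p] <- newh
      return(list(tree = tree, loghr = 0))
    }
    g <- tree$parent[p]
    if (g == 0L) return(NULL)  # topology-changing slide of the root edge:
                               # the reverse climb cannot recreate it
    anc <- tree$parent[node]   # attach p on edge (node, anc)
    tree <- swap_child(tree, g, p, sib)
    tree$parent[sib] <- g
    tree <- swap_child(tree, anc, node, p)
    tree$parent[p] <- anc
    tree <- swap_child(tree, p, sib, node)
    tree$parent[node] <- p
    tree$heights[p] <- newh
    return(list(tree = tree, loghr = k * log(2)))
  }
}

wb_destinations <- function(tree, i, hmin) {
  ## candidate attachment edges (j, parent(j)) with h(parent(j)) > hmin,
  ## j outside the subtree of i and j != parent(i)
  p <- tree$parent[i]
  insub <- logical(tree$nnode)
  mark <- function(v) {
    insub[v] <<- TRUE
    if (v > tree$ntip) { mark(tree$children[v, 1L]); mark(tree$children[v, 2L]) }
  }
  mark(i)
  cand <- integer(0)
  for (j in seq_len(tree$nnode)) {
    pj <- tree$parent[j]
    if (pj == 0L || insub[j] || j == p || pj == p) next
    if (tree$heights[pj] > hmin) cand <- c(cand, j)
  }
  cand
}

#' Wilson-Balding move
#'
#' Detaches the parent edge of a random node and re-grafts it onto a
#' random eligible branch with a uniform new height; the Hastings ratio
#' accounts for the height ranges and destination counts in both
#' directions.  Moves involving the root edge are not proposed.
#'
#' @param tree a `timetree`.
#' @return list with `tree`, `loghr`, or `NULL`.
#' @export
move_wilson_balding <- function(tree) {
  elig <- which(tree$parent != 0L & tree$parent[pmax(tree$parent, 1L)] != 0L)
  elig <- elig[tree$parent[elig] != tree$root]
  if (!length(elig)) return(NULL)
  i <- elig[sample.int(length(elig), 1L)]
  p <- tree$parent[i]
  g <- tree$parent[p]
  sib <- setdiff(tree$children[p, ], i)
  hmin_i <- tree$heights[i]
  dests <- wb_destinations(tree, i, hmin_i)
  if (!length(dests)) return(NULL)
  j <- dests[sample.int(length(dests), 1L)]
  pj <- tree$parent[j]
  range_old <- tree$heights[g] - max(hmin_i, tree$heights[sib])
  range_new <- tree$heights[pj] - max(hmin_i, tree$heights[j])
  newh <- runif(1, max(hmin_i, tree$heights[j]), tree$heights[pj])
  ## detach p
  tree <- swap_child(tree, g, p, sib)
  tree$parent[sib] <- g
  ## attach on (j, pj)
  tree <- swap_child(tree, pj, j, p)
  tree$parent[p] <- pj
  tree <- swap_child(tree, p, sib, j)
  tree$parent[j] <- p
  tree$heights[p] <- newh
  ndest_rev <- length(wb_destinations(tree, i, hmin_i))
  loghr <- log(range_new) - log(range_old) +
    log(length(dests)) - log(ndest_rev)
  list(tree = tree, loghr = loghr)
}
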