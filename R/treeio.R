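#' @useDynLib phylomcmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rexp runif rnorm rgamma rbeta dnorm dgamma dbeta dexp
#'   qgamma pgamma quantile sd var cov rbinom rpois dpois setNames acf
#'   optimize dlnorm median cor
#' @importFrom utils head tail read.table write.table
NULL

## ------------------------------------------------------------------
## TimeTree: rooted binary tree with node heights (time before the
## most recent sampled tip).  Node indexing follows the ape convention:
## tips 1..ntip, internal nodes (ntip+1)..(2*ntip-1).
## ------------------------------------------------------------------

#' Construct a time tree
#'
#' A `timetree` is a rooted, strictly bifurcating phylogeny whose node
#' heights measure time before the most recent sampled tip.  It is the
#' central sampled object of the package: coalescent priors, sequence and
#' trait likelihoods, and the tree transition kernels all operate on it.
#'
#' @param parent integer vector of length `2*ntip - 1`; `parent[v]` is the
#'   parent node of `v`, `0` for the root.
#' @param heights numeric node heights, same length; tips need not be
#'   contemporaneous (serially sampled tips have positive heights).
#' @param tip_label character vector of tip labels (nodes `1..ntip`).
#' @param tip_date optional numeric sampling dates (decimal years) per tip.
#' @param validate check invariants (single root, binary, positive branches).
#' @return an object of class `timetree`.
#' @export
timetree <- function(parent, heights, tip_label, tip_date = NULL,
                     validate = TRUE) {
  ntip <- length(tip_label)
  nnode <- 2L * ntip - 1L
  stopifnot(length(parent) == nnode, length(heights) == nnode)
  parent <- as.integer(parent)
  children <- matrix(0L, nnode, 2L)
  for (v in seq_len(nnode)) {
    p <- parent[v]
    if (p > 0L) {
      if (children[p, 1L] == 0L) children[p, 1L] <- v
      else if (children[p, 2L] == 0L) children[p, 2L] <- v
      else stop("node ", p, " has more than two children")
    }
  }
  root <- which(parent == 0L)
  tr <- structure(list(
    ntip = ntip, nnode = nnode, parent = parent, children = children,
    heights = as.numeric(heights), tip_label = as.character(tip_label),
    tip_date = tip_date, root = root
  ), class = "timetree")
  if (validate) validate_timetree(tr)
  tr
}

#' Validate time-tree invariants
#'
#' Checks single-rootedness, strict bifurcation, strictly positive branch
#' lengths (`h_parent > h_child`) and a zero minimum tip height for
#' contemporaneous trees.
#'
#' @param tree a `timetree`.
#' @param tol numerical slack for the branch-length positivity check.
#' @return the tree, invisibly; stops on violation.
#' @export
validate_timetree <- function(tree, tol = 0) {
  ntip <- tree$ntip
  if (length(tree$root) != 1L)
    stop("tree must have exactly one root, found ", length(tree$root))
  if (anyDuplicated(tree$tip_label))
    stop("duplicate taxon labels: ",
         paste(unique(tree$tip_label[duplicated(tree$tip_label)]),
               collapse = ", "))
  internal <- (ntip + 1L):tree$nnode
  if (any(tree$children[internal, ] == 0L))
    stop("internal nodes must have exactly two children (no polytomies)")
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  bl <- tree$heights[tree$parent[nonroot]] - tree$heights[nonroot]
  if (any(bl <= tol))
    stop("non-positive branch length at node(s) ",
         paste(nonroot[bl <= tol], collapse = ", "))
  if (min(tree$heights[seq_len(ntip)]) < -1e-9)
    stop("negative tip height")
  invisible(tree)
}

#' Postorder sequence of internal nodes
#'
#' @param tree a `timetree`.
#' @return integer vector of internal node ids, children-before-parents.
#' @export
postorder_nodes <- function(tree) {
  ## heights strictly increase from child to parent, so ascending height
  ## order over internal nodes is a valid children-first ordering
  internal <- (tree$ntip + 1L):tree$nnode
  internal[order(tree$heights[internal])]
}

#' Branch length above a node
#' @param tree a `timetree`.
#' @param v node id(s); defaults to all non-root nodes.
#' @return numeric vector `h_parent - h_child`.
#' @export
branch_length <- function(tree, v = setdiff(seq_len(tree$nnode), tree$root)) {
  tree$heights[tree$parent[v]] - tree$heights[v]
}

#' Total tree length (sum of all branch durations)
#' @param tree a `timetree`.
#' @export
tree_length <- function(tree) sum(branch_length(tree))

## -- conversion to/from ape ----------------------------------------

#' Convert a `timetree` to an ape `phylo` object
#' @param tree a `timetree`.
#' @return an ape `phylo`.
#' @export
timetree_to_phylo <- function(tree) {
  nonroot <- setdiff(seq_len(tree$nnode), tree$root)
  ## ape numbers the root ntip+1; remap internal ids so root comes first
  internal <- c(tree$root, setdiff((tree$ntip + 1L):tree$nnode, tree$root))
  remap <- integer(tree$nnode)
  remap[seq_len(tree$ntip)] <- seq_len(tree$ntip)
  remap[internal] <- tree$ntip + seq_along(internal)
  edge <- cbind(remap[tree$parent[nonroot]], remap[nonroot])
  phy <- list(edge = edge,
              edge.length = branch_length(tree, nonroot),
              tip.label = tree$tip_label,
              Nnode = tree$ntip - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape `phylo` to a `timetree`
#'
#' Heights are computed from root-to-tip path lengths; the deepest tip is
#' anchored at height zero.  If sampling dates are available they are
#' checked against the height differences implied by the branch lengths.
#'
#' @param phy an ape `phylo` with edge lengths, rooted and binary.
#' @param date_map optional named numeric vector taxon -> decimal-year date.
#' @param date_tol tolerance for the date/height consistency check.
#' @return a `timetree`.
#' @export
phylo_to_timetree <- function(phy, date_map = NULL, date_tol = 1e-6) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be strictly bifurcating")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length in input tree")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  heights <- max(depth[seq_len(ntip)]) - depth
  parent <- integer(nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  tip_date <- NULL
  if (!is.null(date_map)) {
    miss <- setdiff(phy$tip.label, names(date_map))
    if (length(miss))
      stop("no sampling date for taxa: ", paste(miss, collapse = ", "))
    tip_date <- as.numeric(date_map[phy$tip.label])
    expect_h <- max(tip_date) - tip_date
    if (max(abs(expect_h - heights[seq_len(ntip)])) > date_tol)
      stop("tip dates inconsistent with branch lengths (max discrepancy ",
           format(max(abs(expect_h - heights[seq_len(ntip)]))), ")")
  }
  timetree(parent, heights, phy$tip.label, tip_date = tip_date)
}

## -- Newick / NEXUS ------------------------------------------------

#' Parse a Newick string into a time tree
#'
#' Tip dates may be supplied explicitly through `date_map`, or parsed from
#' trailing `_<decimal year>` suffixes in the taxon labels when
#' `parse_label_dates = TRUE`; an explicit table always wins.
#'
#' @param text a Newick string with branch lengths.
#' @param date_map optional named numeric vector taxon -> date.
#' @param parse_label_dates attempt to read dates from label suffixes.
#' @return a `timetree`.
#' @export
parse_newick <- function(text, date_map = NULL, parse_label_dates = FALSE) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon labels in Newick string")
  if (is.null(date_map) && parse_label_dates) {
    m <- regmatches(phy$tip.label,
                    regexpr("_[0-9]+(\\.[0-9]+)?$", phy$tip.label))
    if (length(m) == length(phy$tip.label) && all(nzchar(m))) {
      date_map <- as.numeric(sub("^_", "", m))
      names(date_map) <- phy$tip.label
    }
  }
  phylo_to_timetree(phy, date_map = date_map)
}

#' Write a time tree as a Newick string
#' @param tree a `timetree`.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(timetree_to_phylo(tree), digits = digits)
}

#' Read a posterior tree sample
#'
#' Accepts a NEXUS trees block (translate tables honored) or plain Newick,
#' one tree per line.
#'
#' @param file path to the tree log.
#' @param format `"nexus"` or `"newick"`.
#' @return a list of `timetree` objects.
#' @export
read_tree_log <- function(file, format = c("nexus", "newick")) {
  format <- match.arg(format)
  trees <- if (format == "nexus") ape::read.nexus(file)
           else ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, phylo_to_timetree)
}

#' Write trees as a NEXUS trees block
#' @param trees list of `timetree` objects.
#' @param file output path.
#' @param tree_names optional names (default `STATE_<i>`).
#' @export
write_tree_log <- function(trees, file, tree_names = NULL) {
  if (is.null(tree_names))
    tree_names <- paste0("STATE_", seq_along(trees) - 1L)
  phys <- lapply(trees, timetree_to_phylo)
  class(phys) <- "multiPhylo"
  names(phys) <- tree_names
  ape::write.nexus(phys, file = file)
}

## -- Alignment -----------------------------------------------------

#' Read a FASTA alignment into a character matrix
#'
#' @param file FASTA path.
#' @return character matrix, taxa in rows (rownames = labels), one column
#'   per site, uppercase.
#' @export
read_fasta_alignment <- function(file) {
  dna <- ape::read.dna(file, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  toupper(dna)
}

#' Read a NEXUS data block into a character matrix
#' @param file NEXUS path (data/characters block).
#' @return character matrix, taxa in rows, uppercase.
#' @export
read_nexus_alignment <- function(file) {
  x <- ape::read.nexus.data(file)
  toupper(do.call(rbind, x))
}

#' Write a character-matrix alignment to FASTA
#' @param aln character matrix with rownames.
#' @param file output path.
#' @export
write_fasta_alignment <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(file)
}

#' Read a tab-delimited trait or date table
#'
#' Expected layout: a header row, first column taxon labels, remaining
#' column(s) the trait value(s) or dates.
#'
#' @param file path.
#' @return data.frame with taxa as rownames.
#' @export
read_trait_table <- function(file) {
  x <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE)
  rownames(x) <- x[[1L]]
  x[, -1L, drop = FALSE]
}

#' Validate an alignment against a tree
#' @param aln character matrix alignment.
#' @param tree a `timetree`.
#' @return invisibly `TRUE`; stops on mismatch.
#' @export
check_alignment <- function(aln, tree) {
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("alignment taxa must be uniquely labelled")
  if (!setequal(rownames(aln), tree$tip_label))
    stop("alignment taxa do not match tree tips")
  invisible(TRUE)
}

## -- Site patterns -------------------------------------------------

#' Compress alignment columns into weighted unique site patterns
#'
#' @param aln character matrix (taxa x sites).
#' @param site_range integer vector of column indices (default all).
#' @return a `patternset`: list with `patterns` (taxa x npattern character
#'   matrix), `weights` (integer), `taxa`, `nsite`.
#' @export
compress_patterns <- function(aln, site_range = seq_len(ncol(aln))) {
  if (nrow(aln) == 0L || length(site_range) == 0L)
    stop("empty alignment or site range")
  sub <- aln[, site_range, drop = FALSE]
  key <- apply(sub, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[first])))
  structure(list(patterns = sub[, first, drop = FALSE],
                 weights = w,
                 taxa = rownames(aln),
                 nsite = length(site_range)),
            class = "patternset")
}

## -- MCC summarization ---------------------------------------------

clade_keys <- function(tree, taxa) {
  ## bitset-like exact clade keys: sorted tip indices in a fixed taxon order
  idx <- match(tree$tip_label, taxa)
  keys <- character(tree$nnode)
  tipsets <- vector("list", tree$nnode)
  for (v in seq_len(tree$ntip)) tipsets[[v]] <- idx[v]
  for (v in postorder_nodes(tree)) {
    s <- sort(c(tipsets[[tree$children[v, 1L]]],
                tipsets[[tree$children[v, 2L]]]))
    tipsets[[v]] <- s
    keys[v] <- paste(s, collapse = ",")
  }
  list(keys = keys, tipsets = tipsets)
}

#' Maximum clade credibility tree
#'
#' Selects, from a posterior sample, the tree that maximizes the product of
#' the posterior frequencies of its clades, and annotates each internal
#' node with its clade support and the mean node height over the trees
#' containing that clade.
#'
#' @param trees list of `timetree` objects on an identical taxon set.
#' @param burnin_fraction fraction of initial trees discarded before
#'   scoring.  No default burn-in convention is claimed; the caller must
#'   choose.
#' @return the selected `timetree` with elements `clade_support` and
#'   `mean_height` (length `nnode`, `NA` for tips) and `log_clade_score`.
#' @export
mcc_tree <- function(trees, burnin_fraction) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1)
  n0 <- length(trees)
  trees <- trees[(floor(burnin_fraction * n0) + 1L):n0]
  if (length(trees) < 2L) stop("need at least 2 post-burnin trees")
  taxa <- sort(trees[[1L]]$tip_label)
  for (tr in trees)
    if (!identical(sort(tr$tip_label), taxa))
      stop("trees have inconsistent taxon sets")
  n <- length(trees)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  hsum <- new.env(hash = TRUE, parent = emptyenv())
  allkeys <- vector("list", n)
  for (i in seq_len(n)) {
    ck <- clade_keys(trees[[i]], taxa)
    internal <- (trees[[i]]$ntip + 1L):trees[[i]]$nnode
    allkeys[[i]] <- ck$keys
    for (v in internal) {
      k <- ck$keys[v]
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      hsum[[k]] <- (if (is.null(hsum[[k]])) 0 else hsum[[k]]) +
        trees[[i]]$heights[v]
    }
  }
  score <- function(i) {
    internal <- (trees[[i]]$ntip + 1L):trees[[i]]$nnode
    sum(log(vapply(allkeys[[i]][internal],
                   function(k) counts[[k]] / n, numeric(1))))
  }
  scores <- vapply(seq_len(n), score, numeric(1))
  best <- which.max(scores)
  out <- trees[[best]]
  support <- rep(NA_real_, out$nnode)
  mheight <- rep(NA_real_, out$nnode)
  for (v in (out$ntip + 1L):out$nnode) {
    k <- allkeys[[best]][v]
    support[v] <- counts[[k]] / n
    mheight[v] <- hsum[[k]] / counts[[k]]
  }
  out$clade_support <- support
  out$mean_height <- mheight
  out$log_clade_score <- scores[best]
  out
}

#' @export
print.timetree <- function(x, ...) {
  cat("timetree:", x$ntip, "tips, root height",
      format(x$heights[x$root], digits = 6), "\n")
  invisible(x)
}
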