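#' @importFrom stats lm coef quantile setNames optim rlnorm runif
#' @importFrom utils read.delim write.table
NULL

# Relative tolerance (fraction of root age) below which root-to-tip depth
# spread is treated as rounding noise from digitised figures.
ULTRAMETRIC_RTOL <- 1e-4

#' Node ages of an ultrametric timetree
#'
#' Ages are measured in millions of years (myr) before present: tips are at
#' age 0 and the root carries the crown age. For inputs whose root-to-tip
#' depths differ by rounding noise, each node's age is the mean path length
#' from the node to its descendant tips, so small inconsistencies are
#' averaged out rather than propagated.
#'
#' @param tree a rooted ultrametric \code{phylo} object with branch lengths.
#' @return numeric vector of length \code{Ntip + Nnode}, indexed by ape node
#'   number; tips are exactly 0.
#' @export
node_ages <- function(tree) {
  h <- mean_path_heights(tree)
  h[seq_len(ape::Ntip(tree))] <- 0
  h
}

# Mean path length from each node to its descendant tips, with a bottom-up
# parent-max pass so heights never decrease toward the root. Shared by
# node_ages() (timetrees) and relative_depths() (untimed trees).
mean_path_heights <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  sums <- numeric(ntot)
  counts <- numeric(ntot)
  counts[seq_len(ntip)] <- 1
  # postorder over edges: children always precede parents
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1L]
    ch <- eo$edge[i, 2L]
    sums[par] <- sums[par] + sums[ch] + counts[ch] * eo$edge.length[i]
    counts[par] <- counts[par] + counts[ch]
  }
  h <- sums / counts
  # enforce monotonicity (parent at least as high as any child)
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1L]
    ch <- eo$edge[i, 2L]
    if (h[par] < h[ch]) h[par] <- h[ch]
  }
  h
}

# Rebuild edge lengths of `tree` from a vector of node ages.
ages_to_edges <- function(tree, ages) {
  len <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  if (any(len < 0)) {
    bad <- which.min(len)
    stop("nonpositive branch: node ", tree$edge[bad, 2L],
         " is older than its parent (", format(-len[bad]), " myr)")
  }
  tree$edge.length <- len
  tree
}

#' Read a Newick tree
#'
#' Reads a rooted tree with branch lengths from a Newick string or file.
#' With \code{timed = TRUE} the tree is validated as ultrametric (branch
#' lengths in myr, all tips at the present): root-to-tip depths must agree
#' to within a relative tolerance of 1e-4 of the root age, and node ages are
#' then rebuilt from mean root-to-tip path lengths so rounding noise in
#' digitised source trees does not accumulate.
#'
#' @param file path to a Newick file (one tree); exactly one of \code{file}
#'   and \code{text} must be given.
#' @param text a Newick string.
#' @param timed logical; validate and age-annotate as a timetree.
#' @return a \code{phylo} object. For \code{timed = TRUE} the branch lengths
#'   are readjusted so the tree is exactly ultrametric.
#' @export
read_newick <- function(file = NULL, text = NULL, timed = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'file' or 'text'")
  tree <- if (!is.null(text)) ape::read.tree(text = text)
          else ape::read.tree(file = file)
  if (is.null(tree)) stop("malformed Newick input")
  if (is.null(tree$edge.length)) stop("Newick input lacks branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in input")
  labs <- tree$tip.label
  if (anyDuplicated(labs)) stop("duplicate tip labels: ",
                                paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (any(!nzchar(labs))) stop("empty tip label in input")
  if (timed) {
    depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
    spread <- max(depth) - min(depth)
    if (spread > ULTRAMETRIC_RTOL * max(depth)) {
      stop("tree is not ultrametric: tips ", labs[which.max(depth)], " and ",
           labs[which.min(depth)], " differ in root-to-tip depth by ",
           format(spread))
    }
    tree <- ages_to_edges(tree, node_ages(tree))
  }
  tree
}

#' Write a tree as Newick
#'
#' Serialises a \code{phylo} object to Newick with branch lengths printed at
#' fixed 6-decimal precision. Trees must have at least two tips (a
#' single-species tree has no internal structure to serialise).
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; when given, the string is written there.
#' @param digits decimal places for branch lengths.
#' @return the Newick string, invisibly when \code{file} is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  if (ape::Ntip(tree) < 2) stop("cannot serialise a tree with fewer than 2 tips")
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  fmt <- paste0("%.", digits, "f")
  rec <- function(node) {
    if (node <= ntip) {
      paste0(tree$tip.label[node], ":", sprintf(fmt, elen[node]))
    } else {
      inner <- paste(vapply(kids[[as.character(node)]], rec, character(1)),
                     collapse = ",")
      paste0("(", inner, ")",
             if (node == ntip + 1L) "" else paste0(":", sprintf(fmt, elen[node])))
    }
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Pendant lengths (terminal branch lengths)
#'
#' For an ultrametric tree the pendant length (PL) of a tip equals the age
#' of its parent node, i.e. the time since its most recent divergence.
#'
#' @param tree an ultrametric \code{phylo}.
#' @return named numeric vector, one PL (myr) per tip.
#' @export
pendant_lengths <- function(tree) {
  ntip <- ape::Ntip(tree)
  pl <- numeric(ntip)
  tip_edges <- match(seq_len(ntip), tree$edge[, 2L])
  pl <- tree$edge.length[tip_edges]
  names(pl) <- tree$tip.label
  pl
}

#' Crown age of a timetree
#'
#' @param tree an ultrametric \code{phylo}.
#' @return the root age in myr (the maximum node age).
#' @export
crown_age <- function(tree) {
  max(node_ages(tree))
}

#' Most recent common ancestor of a set of taxa
#'
#' @param tree a \code{phylo}.
#' @param taxa character vector of tip labels (length >= 1).
#' @return the ape node number of the MRCA (the tip itself for one taxon).
#' @export
tree_mrca <- function(tree, taxa) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxon: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Remove tips from a tree
#'
#' Degree-2 nodes left by the removal are suppressed and their branch
#' lengths summed, so all pairwise divergence times among surviving tips
#' are unchanged.
#'
#' @param tree a \code{phylo}.
#' @param tips tip labels to drop.
#' @return the pruned \code{phylo}.
#' @export
prune_tips <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxon: ", paste(tips[is.na(idx)], collapse = ", "))
  if (ape::Ntip(tree) - length(tips) < 2)
    stop("pruning would leave fewer than 2 tips")
  ape::drop.tip(tree, tips)
}

#' Sister clade of a tip
#'
#' @param tree a \code{phylo}.
#' @param tip a tip label.
#' @return character vector of the tip labels in the other child clade of
#'   the tip's parent node.
#' @export
find_sister <- function(tree, tip) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown taxon: ", tip)
  parent <- tree$edge[tree$edge[, 2L] == i, 1L]
  sibs <- tree$edge[tree$edge[, 1L] == parent, 2L]
  sibs <- sibs[sibs != i]
  unlist(lapply(sibs, function(s) {
    if (s <= ape::Ntip(tree)) tree$tip.label[s]
    else tree$tip.label[unlist(phangorn::Descendants(tree, s, "tips"))]
  }), use.names = FALSE)
}

# Internal: tip labels descending from each node, as a list keyed by node id.
clade_tip_sets <- function(tree) {
  desc <- phangorn::Descendants(tree, seq_len(ape::Ntip(tree) + tree$Nnode), "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

#' Check that a tree is an ultrametric timetree
#'
#' @param tree a \code{phylo}.
#' @param tol absolute tolerance in myr on root-to-tip depth spread.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
assert_ultrametric <- function(tree, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (max(depth) - min(depth) > tol)
    stop("tree is not ultrametric (depth spread ", format(max(depth) - min(depth)), ")")
  invisible(TRUE)
}
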