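# Secondary-calibration dating of untimed phylogenies, plus the small
# sequence-to-tree prong (coverage filter, JC distances, neighbor joining).

#' Relative node depths of an untimed phylogeny
#'
#' Each node's height is its mean path length to its descendant tips (in the
#' tree's substitution units); heights are made monotone by a bottom-up
#' parent-max pass and divided by the root height, so the root maps to 1 and
#' tips map to 0. On a strict-clock tree the relative depths equal true node
#' ages divided by the crown age exactly.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @return numeric vector over node numbers (tips first), in [0, 1].
#' @export
relative_depths <- function(tree) {
  h <- mean_path_heights(tree)
  ntip <- ape::Ntip(tree)
  h[seq_len(ntip)] <- 0
  root_h <- h[ntip + 1L]
  if (root_h <= 0) stop("zero-height tree: no branch length signal to scale")
  h / root_h
}

#' Read a calibration table
#'
#' Tab-delimited text with header \code{taxon_a, taxon_b, min_myr, max_myr};
#' each row is a uniform age range for the MRCA of the two taxa.
#'
#' @param file path.
#' @return data frame of calibration constraints.
#' @export
read_calibration_table <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("taxon_a", "taxon_b", "min_myr", "max_myr")
  if (!all(need %in% names(x)))
    stop("calibration table must have columns: ", paste(need, collapse = ", "))
  x
}

#' Date an untimed phylogeny with uniform secondary calibrations
#'
#' Converts relative node depths (\code{\link{relative_depths}}) to absolute
#' ages in myr. Uniform \code{[min, max]} calibrations are summarised by
#' their midpoints: with one constraint the global scale makes the
#' calibrated node's age equal the midpoint; with several, the scale is the
#' least-squares fit of depth times scale to the midpoints. Any calibrated
#' node then falling outside its range is clamped to the nearest bound, its
#' descendants rescaled proportionally, and the ages between it and the root
#' remapped linearly.
#'
#' @param tree rooted \code{phylo} with substitution branch lengths.
#' @param constraints data frame with columns \code{taxon_a, taxon_b,
#'   min_myr, max_myr} (see \code{\link{read_calibration_table}}).
#' @return an ultrametric \code{phylo} with branch lengths in myr.
#' @export
calibrate_tree <- function(tree, constraints) {
  if (is.null(constraints) || nrow(constraints) == 0L)
    stop("at least one calibration constraint is required")
  if (!all(constraints$min_myr >= 0 & constraints$min_myr < constraints$max_myr))
    stop("each constraint needs 0 <= min_myr < max_myr")
  nodes <- vapply(seq_len(nrow(constraints)), function(i)
    tree_mrca(tree, c(constraints$taxon_a[i], constraints$taxon_b[i])),
    numeric(1))
  # same node constrained twice must have overlapping ranges
  for (nd in unique(nodes[duplicated(nodes)])) {
    rng <- constraints[nodes == nd, ]
    if (max(rng$min_myr) >= min(rng$max_myr))
      stop("disjoint calibration ranges on the same node (node ", nd, ")")
  }
  rd <- relative_depths(tree)
  mid <- (constraints$min_myr + constraints$max_myr) / 2
  d <- rd[nodes]
  if (any(d == 0)) stop("calibration on a zero-depth node")
  s <- sum(d * mid) / sum(d^2)  # least squares through the origin
  ages <- rd * s
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  # clamp violated constraints to the nearest bound, applying a monotone
  # piecewise-linear remap of all ages: proportional below the clamped node,
  # linear between it and the root (order among nodes is preserved, so the
  # tree stays ultrametric with positive branches). A remap can displace a
  # previously satisfied node, so passes repeat until all constraints hold.
  for (pass in 1:100) {
    changed <- FALSE
    for (i in seq_len(nrow(constraints))) {
      nd <- nodes[i]
      a <- ages[nd]
      lo <- constraints$min_myr[i]; hi <- constraints$max_myr[i]
      tol <- 1e-9 * max(hi, 1)  # nodes resting on a bound are in range
      if (a >= lo - tol && a <= hi + tol) next
      changed <- TRUE
      new <- if (a < lo) lo else hi
      root_age <- ages[root]
      if (nd == root) {
        ages <- ages * (new / a)
      } else {
        below <- ages <= a
        ages[below] <- ages[below] * (new / a)
        ages[!below] <- new + (ages[!below] - a) * (root_age - new) / (root_age - a)
      }
    }
    if (!changed) break
  }
  if (changed)
    warning("calibration clamping did not settle after 100 passes; ",
            "some node ages may sit outside their ranges")
  ages[seq_len(ntip)] <- 0
  ages_to_edges(tree, ages)
}

#' Remove low-coverage alignment columns
#'
#' Drops columns whose proportion of informative cells (not gap, not N/?) is
#' below \code{threshold}; the order of surviving columns is preserved.
#'
#' @param aln character matrix (rows = taxa).
#' @param threshold minimum informative proportion a column must reach to be
#'   kept (default 0.5).
#' @return the filtered character matrix.
#' @export
filter_coverage <- function(aln, threshold = 0.5) {
  stopifnot(is.matrix(aln), threshold >= 0, threshold <= 1)
  informative <- !(tolower(aln) %in% c("-", "n", "?"))
  dim(informative) <- dim(aln)
  keep <- colMeans(informative) >= threshold
  if (!any(keep))
    stop("all columns fall below the coverage threshold of ", threshold)
  aln[, keep, drop = FALSE]
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise JC69 distances, d = -(3/4) log(1 - 4p/3), with pairwise deletion
#' of gap/ambiguous sites. Saturated pairs (p >= 0.75) are an error.
#'
#' @param aln character matrix (rows = taxa).
#' @return a \code{dist} object.
#' @export
jc_distance <- function(aln) {
  d <- ape::dist.dna(ape::as.DNAbin(aln), model = "JC69",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d)))
    stop("saturated sequence pair (proportion of differences >= 0.75); ",
         "JC correction undefined")
  d
}

#' Neighbor-joining tree with negative-branch repair
#'
#' Standard NJ agglomeration; any negative branch length is clamped to zero
#' and its deficit transferred to the adjacent branches (the child's
#' outgoing edges, or the parent's incoming edge for a terminal branch), so
#' path lengths through the node are approximately preserved. Optionally
#' rooted on an outgroup.
#'
#' @param dist a \code{dist} object or symmetric matrix.
#' @param outgroup optional tip label to root on.
#' @return an unrooted (or outgroup-rooted) \code{phylo}.
#' @export
nj_tree <- function(dist, outgroup = NULL) {
  tr <- ape::nj(dist)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    ch <- tr$edge[e, 2L]
    if (ch > ape::Ntip(tr)) {
      down <- which(tr$edge[, 1L] == ch)
      tr$edge.length[down] <- pmax(0, tr$edge.length[down] + deficit)
    } else {
      up <- which(tr$edge[, 2L] == tr$edge[e, 1L])
      if (length(up)) tr$edge.length[up] <- max(0, tr$edge.length[up] + deficit)
    }
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not in tree: ", outgroup)
    tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  }
  tr
}
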