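# Audit metrics: equal-splits evolutionary isolation, crown-age scaling,
# and node-age / pendant-length regressions between chronograms.

#' Equal-splits evolutionary isolation
#'
#' The equal-splits statistic apportions every branch among its descendant
#' tips, halving the inherited share at each bifurcation on the way down, so
#' a tip's EI (in myr) is the sum over its root-path edges of
#' length / 2^(number of internal nodes between that edge and the tip). On a
#' binary tree the tip EIs sum exactly to the total branch length.
#' Normalised EI divides by the crown age, making values comparable between
#' trees dated under different calibration schemes.
#'
#' @param tree binary ultrametric \code{phylo}.
#' @return data frame (class \code{ei_report}) with columns \code{species},
#'   \code{ei} and \code{ei_normalized}, and attribute \code{crown_age}.
#' @export
equal_splits <- function(tree) {
  ntip <- ape::Ntip(tree)
  deg <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  poly <- which(deg > 2L)
  if (length(poly))
    stop("tree has a polytomy at node ", poly[1L],
         "; equal splits requires a binary tree")
  acc <- numeric(ntip + tree$Nnode)
  eo <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1L]; ch <- eo$edge[i, 2L]
    acc[ch] <- acc[par] / 2 + eo$edge.length[i]
  }
  ei <- acc[seq_len(ntip)]
  crown <- crown_age(tree)
  out <- data.frame(species = tree$tip.label, ei = ei,
                    ei_normalized = ei / crown)
  attr(out, "crown_age") <- crown
  class(out) <- c("ei_report", "data.frame")
  out
}

ols_pairs <- function(x, y) {
  if (length(x) < 3L) stop("regression needs at least 3 pairs")
  fit <- lm(y ~ x)
  rev_fit <- lm(x ~ y)
  # r^2 computed directly; summary.lm warns on exact fits
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    pairs = data.frame(x = x, y = y),
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    reverse = list(slope = unname(coef(rev_fit)[2L]),
                   intercept = unname(coef(rev_fit)[1L]))
  ), class = "tree_regression")
}

#' @export
print.tree_regression <- function(x, ...) {
  cat(sprintf("tree regression over %d pairs: slope = %.4f, intercept = %.4f, R^2 = %.4f\n",
              nrow(x$pairs), x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Node-age agreement between two timetrees
#'
#' Matches internal nodes whose clades, restricted to the shared taxon set,
#' occur in both trees (so taxa unique to one tree never block a match), and
#' regresses the ages in \code{tree_b} on those in \code{tree_a} by OLS.
#'
#' @param tree_a,tree_b ultrametric \code{phylo} trees with >= 3 shared
#'   matched nodes.
#' @return a \code{tree_regression}: matched age pairs, slope, intercept,
#'   R-squared (and the reverse-order fit).
#' @export
shared_node_ages <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 3L) stop("trees share fewer than 3 taxa")
  ages_a <- node_ages(tree_a); ages_b <- node_ages(tree_b)
  sets_a <- clade_tip_sets(tree_a); sets_b <- clade_tip_sets(tree_b)
  ntip_a <- ape::Ntip(tree_a)
  xs <- ys <- numeric(0)
  for (j in seq_len(tree_a$Nnode)) {
    nd <- ntip_a + j
    S <- intersect(sets_a[[nd]], shared)
    if (length(S) < 2L) next
    if (ape::getMRCA(tree_a, match(S, tree_a$tip.label)) != nd) next
    m <- ape::getMRCA(tree_b, match(S, tree_b$tip.label))
    if (!setequal(intersect(sets_b[[m]], shared), S)) next
    xs <- c(xs, ages_a[nd]); ys <- c(ys, ages_b[m])
  }
  if (length(xs) < 3L) stop("fewer than 3 shared nodes between the trees")
  ols_pairs(xs, ys)
}

#' Pendant-length agreement between two timetrees
#'
#' Pairs the pendant lengths of shared tips, optionally dividing each by its
#' own tree's crown age (the scaling that makes trees dated under different
#' calibration schemes comparable), and fits an OLS regression.
#'
#' @param tree_a,tree_b ultrametric \code{phylo} trees with >= 3 shared tips.
#' @param scale_by_crown divide each tree's PLs by its crown age.
#' @return a \code{tree_regression}.
#' @export
compare_pendant_lengths <- function(tree_a, tree_b, scale_by_crown = FALSE) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 3L) stop("trees share fewer than 3 tips")
  pa <- pendant_lengths(tree_a)[shared]
  pb <- pendant_lengths(tree_b)[shared]
  if (scale_by_crown) {
    pa <- pa / crown_age(tree_a)
    pb <- pb / crown_age(tree_b)
  }
  res <- ols_pairs(unname(pa), unname(pb))
  rownames(res$pairs) <- shared
  res
}

#' Compare two normalised-EI distributions
#'
#' Summarises each report's normalised EI distribution by its deciles and
#' reports decile differences; when the reports share tips, per-species
#' paired differences are reported as well.
#'
#' @param report_a,report_b \code{ei_report} objects from
#'   \code{\link{equal_splits}}.
#' @return list with \code{deciles_a}, \code{deciles_b}, \code{decile_diff}
#'   (b minus a), and, when tip sets overlap, \code{paired} (species-wise
#'   differences) and \code{median_paired_diff}.
#' @export
ei_distribution_summary <- function(report_a, report_b) {
  if (nrow(report_a) == 0L || nrow(report_b) == 0L)
    stop("empty EI report")
  probs <- seq(0.1, 0.9, by = 0.1)
  qa <- quantile(report_a$ei_normalized, probs, names = TRUE)
  qb <- quantile(report_b$ei_normalized, probs, names = TRUE)
  out <- list(deciles_a = qa, deciles_b = qb, decile_diff = qb - qa,
              paired = NULL, median_paired_diff = NA_real_)
  shared <- intersect(report_a$species, report_b$species)
  if (length(shared)) {
    da <- setNames(report_a$ei_normalized, report_a$species)[shared]
    db <- setNames(report_b$ei_normalized, report_b$species)[shared]
    out$paired <- data.frame(species = shared, diff = unname(db - da))
    out$median_paired_diff <- stats::median(db - da)
  }
  out
}

#' Check a reference expanded timetree
#'
#' Computes the headline summaries of a published expanded timetree from its
#' Newick file: tip count, crown age, the EI of a named focal species, and
#' the mean EI over a named genus.
#'
#' @param file path to the reference Newick.
#' @param focal_species tip whose EI is reported.
#' @param genus genus whose tips' mean EI is reported.
#' @return list with \code{n_tips}, \code{crown_age}, \code{focal_ei},
#'   \code{genus_mean_ei}.
#' @export
validate_reference_tree <- function(file, focal_species = "Homo_sapiens",
                                    genus = "Macaca") {
  tree <- read_newick(file = file, timed = TRUE)
  rep <- equal_splits(tree)
  ei <- setNames(rep$ei, rep$species)
  in_genus <- startsWith(rep$species, paste0(genus, "_"))
  list(n_tips = ape::Ntip(tree),
       crown_age = crown_age(tree),
       focal_ei = unname(ei[focal_species]),
       genus_mean_ei = mean(ei[in_genus]))
}
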