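# Synthetic data with known ground truth: birth-death timetrees, invertible
# prune-regraft scenarios, rate-varying branch lengths, and toy alignments.

#' Simulate a birth-death timetree
#'
#' Forward birth-death simulation conditioned on the number of surviving
#' tips, with extinct lineages pruned, so the result is an ultrametric
#' timetree of exactly \code{n_tips} extant species. Simulation is retried
#' (bounded) when extinction terminates a replicate early.
#'
#' @param lambda speciation rate (events/lineage/myr), > mu.
#' @param mu extinction rate (events/lineage/myr), >= 0.
#' @param n_tips number of surviving tips (>= 3).
#' @param seed integer seed; the same seed always yields the same tree.
#' @return an ultrametric \code{phylo} with \code{n_tips} tips.
#' @export
simulate_bd_tree <- function(lambda, mu = 0, n_tips, seed) {
  stopifnot(lambda > mu, mu >= 0, n_tips >= 3)
  set.seed(seed)
  for (try in 1:200) {
    tr <- tryCatch(
      phytools::pbtree(b = lambda, d = mu, n = n_tips, extant.only = TRUE,
                       quiet = TRUE),
      error = function(e) NULL)
    if (!is.null(tr) && ape::Ntip(tr) == n_tips &&
        ape::is.ultrametric(tr, option = 2)) {
      tr <- ages_to_edges(tr, node_ages(tr))  # exact ultrametry
      return(tr)
    }
  }
  stop("birth-death simulation failed after 200 attempts (mu too close to lambda?)")
}

#' Build an invertible prune-regraft scenario
#'
#' Sequentially prunes \code{k} tips from a known timetree, at each step
#' choosing (uniformly) a tip whose current sister is a single tip, and
#' records the instruction that restores it: sister anchor = that tip,
#' pendant length = the pruned tip's attachment-node age. Instructions are
#' returned in reverse prune order, so applying them in order with
#' \code{\link{apply_grafts}} reconstructs the original tree exactly when
#' \code{conflict_fraction = 0}. A fraction of instructions have their PL
#' inflated to 1.5 times the anchor's pendant length at application time
#' (determined by an internal replay), guaranteeing the polytomy-avoidance
#' conflict rule fires for them.
#'
#' @param tree ultrametric \code{phylo} ground truth.
#' @param k number of tips to prune (\code{k <= Ntip - 3}).
#' @param conflict_fraction proportion of instructions whose PL is inflated
#'   to force the conflict rule.
#' @param seed integer seed.
#' @return list of class \code{graft_scenario}: \code{truth},
#'   \code{backbone}, \code{instructions} (ready for
#'   \code{\link{apply_grafts}}), and \code{conflicted} (logical per
#'   instruction row).
#' @export
make_graft_scenario <- function(tree, k, conflict_fraction = 0, seed) {
  stopifnot(k >= 0, k <= ape::Ntip(tree) - 3,
            conflict_fraction >= 0, conflict_fraction <= 1)
  set.seed(seed)
  cur <- tree
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    sisters <- vapply(cur$tip.label, function(tp) {
      s <- find_sister(cur, tp)
      if (length(s) == 1L) s else NA_character_
    }, character(1))
    cand <- names(sisters)[!is.na(sisters)]
    x <- cand[sample.int(length(cand), 1L)]
    pl <- unname(pendant_lengths(cur)[x])
    cur <- prune_tips(cur, x)
    rows[[i]] <- data.frame(species = x, mode = "sister",
                            anchor = unname(sisters[x]), pl_myr = pl,
                            source = "scenario")
  }
  instructions <- if (k > 0) do.call(rbind, rev(rows)) else
    data.frame(species = character(), mode = character(), anchor = character(),
               pl_myr = numeric(), source = character())
  to_inflate <- rep(FALSE, k)
  n_conf <- round(conflict_fraction * k)
  if (n_conf > 0) to_inflate[sample.int(k, n_conf)] <- TRUE
  conflicted <- rep(FALSE, k)
  if (n_conf > 0) {
    # replay: inflate each marked instruction against the anchor's pendant
    # length in the tree state it will actually be applied to
    state <- cur
    for (i in seq_len(k)) {
      ins <- instructions[i, ]
      if (to_inflate[i])
        instructions$pl_myr[i] <- 1.5 * unname(pendant_lengths(state)[ins$anchor])
      res <- graft_tip(state, ins$species, ins$anchor, instructions$pl_myr[i],
                       mode = "sister")
      state <- res$tree
      conflicted[i] <- identical(res$record$rule, "conflict_offset")
    }
  }
  structure(list(truth = tree, backbone = cur, instructions = instructions,
                 conflicted = conflicted),
            class = "graft_scenario")
}

#' Impose lognormal rate variation on a timetree
#'
#' Converts a chronogram (branch durations in myr) into an untimed phylogeny
#' whose branch lengths are duration times an i.i.d. lognormal per-branch
#' rate with mean 1 and log-scale standard deviation \code{sigma}.
#' \code{sigma = 0} gives a strict clock: branch lengths equal durations.
#'
#' @param tree ultrametric \code{phylo}.
#' @param sigma lognormal sd of per-branch rates (>= 0).
#' @param seed integer seed.
#' @return a \code{phylo} with branch lengths in substitution-like units.
#' @export
apply_rate_variation <- function(tree, sigma, seed) {
  stopifnot(sigma >= 0)
  set.seed(seed)
  rates <- rlnorm(nrow(tree$edge), meanlog = -sigma^2 / 2, sdlog = sigma)
  tree$edge.length <- tree$edge.length * rates
  tree
}

#' Simulate a toy alignment under Jukes-Cantor
#'
#' Evolves nucleotide sequences along a phylogeny under the Jukes-Cantor
#' model (branch lengths in expected substitutions/site), then replaces a
#' fraction of cells by gap symbols to emulate missing data.
#'
#' @param tree \code{phylo} with substitution branch lengths.
#' @param length number of sites (>= 1).
#' @param missing_fraction proportion of matrix cells replaced by \code{"-"}.
#' @param seed integer seed.
#' @return character matrix (rows = taxa, columns = sites) of
#'   \code{a/c/g/t/-}.
#' @export
simulate_alignment <- function(tree, length, missing_fraction = 0, seed) {
  stopifnot(length >= 1, missing_fraction >= 0, missing_fraction < 1)
  set.seed(seed)
  aln <- as.character(phangorn::simSeq(tree, l = length, type = "DNA"))
  if (missing_fraction > 0) {
    n_cells <- base::length(aln)
    holes <- sample.int(n_cells, round(missing_fraction * n_cells))
    aln[holes] <- "-"
  }
  aln
}

#' Write an alignment as FASTA
#'
#' @param aln character matrix with taxon rownames.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(aln, file) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1L, paste, collapse = "")
  writeLines(lines, file)
  invisible(file)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param file FASTA path (aligned, equal-length sequences).
#' @return character matrix (rows = taxa), lower case.
#' @export
read_fasta <- function(file) {
  x <- ape::read.FASTA(file)
  m <- as.character(as.matrix(x))
  rownames(m) <- names(x)
  m
}
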