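# Shared fixtures and independent oracles.

# the three-tip worked example used throughout: root age 2, cherry at 1
tree3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")

topo_identical <- function(a, b) {
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE))
}

max_age_error <- function(a, b) {
  max(abs(sort(unname(ape::branching.times(a))) -
          sort(unname(ape::branching.times(b)))))
}

# Independent equal-splits oracle: explicit root-path enumeration per tip,
# halving each successive edge share walking rootward.
es_bruteforce <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  vapply(seq_len(ntip), function(tip) {
    v <- 0; node <- tip; div <- 1
    while (node != root) {
      v <- v + elen[node] / div
      node <- parent[node]
      div <- div * 2
    }
    v
  }, numeric(1))
}

# A calibration constraint spanning the root: one tip from each child clade.
root_constraint <- function(tree, min_myr, max_myr) {
  ntip <- ape::Ntip(tree)
  kids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  pick <- function(k) {
    if (k <= ntip) k else unlist(phangorn::Descendants(tree, k, "tips"))[1]
  }
  data.frame(taxon_a = tree$tip.label[pick(kids[1])],
             taxon_b = tree$tip.label[pick(kids[2])],
             min_myr = min_myr, max_myr = max_myr)
}
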