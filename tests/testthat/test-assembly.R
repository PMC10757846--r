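test_that("sister grafting follows the worked placement rules", {
  bb <- read_newick(text = "((A:5,C:5):5,E:10);")
  # requested PL below the anchor's: attach at the requested age
  g1 <- graft_tip(bb, "B", "A", pl = 3)
  expect_identical(write_newick(g1$tree),
                   "(((A:3.000000,B:3.000000):2.000000,C:5.000000):5.000000,E:10.000000);")
  expect_identical(g1$record$rule, "as_given")
  # requested PL >= anchor's: both species get the anchor PL minus 0.1
  g2 <- graft_tip(bb, "D", "C", pl = 7)
  expect_identical(g2$record$rule, "conflict_offset")
  expect_equal(unname(pendant_lengths(g2$tree)[c("C", "D")]), c(4.9, 4.9))
  expect_equal(g2$record$attachment_age, 4.9)
  expect_true(assert_ultrametric(g2$tree))
  expect_true(ape::is.binary(g2$tree))
})

test_that("genus-base grafting attaches at the stem midpoint", {
  bb <- read_newick(text = "((Ge_a:5,Ge_c:5):5,Ot_e:10);")
  g <- graft_tip(bb, "Ge_x", "Ge", mode = "genus_base")
  expect_equal(g$record$attachment_age, 7.5)  # midpoint of crown 5 and stem 10
  expect_true(assert_ultrametric(g$tree))
  # single-member genus: midpoint of the tip's own branch
  g2 <- graft_tip(bb, "Ot_x", "Ot", mode = "genus_base")
  expect_equal(g2$record$attachment_age, 5)
  # genus spanning the whole tree has no stem
  expect_error(graft_tip(read_newick(text = "(Ge_a:5,Ge_b:5);"), "Ge_x", "Ge",
                         mode = "genus_base"), "stem")
})

test_that("grafting errors are informative and leave the backbone usable", {
  bb <- read_newick(text = "((A:5,C:5):5,E:10);")
  expect_error(graft_tip(bb, "A", "C", pl = 1), "already in tree")
  expect_error(graft_tip(bb, "X", "Z", pl = 1), "anchor not in tree")
  # anchor PL shorter than the offset cannot host a conflict graft
  short <- graft_tip(bb, "B", "A", pl = 0.05)$tree
  expect_error(graft_tip(short, "B2", "A", pl = 9), "too short")
})

test_that("graft_tip leaves pre-existing divergence times untouched", {
  tr <- simulate_bd_tree(0.2, 0, 30, seed = 11)
  before <- ape::cophenetic.phylo(tr)
  g <- graft_tip(tr, "New_sp", tr$tip.label[1],
                 pl = pendant_lengths(tr)[1] / 2)$tree
  after <- ape::cophenetic.phylo(g)[rownames(before), colnames(before)]
  expect_lt(max(abs(before - after)), 1e-12)
})

test_that("apply_grafts applies in order, aggregates errors, conserves counts", {
  bb <- read_newick(text = "((A:5,C:5):5,E:10);")
  # empty list: unchanged
  res0 <- apply_grafts(bb, NULL)
  expect_identical(write_newick(res0$tree), write_newick(bb))
  expect_equal(nrow(res0$report$grafted), 0)
  # sequential anchoring on the same sister: second lands inside the first cherry
  ins <- data.frame(species = c("B1", "B2"), mode = "sister", anchor = "A",
                    pl_myr = c(4, 3), source = "")
  res <- apply_grafts(bb, ins)
  expect_equal(ape::Ntip(res$tree), 5)
  expect_true(assert_ultrametric(res$tree))
  expect_true(ape::is.binary(res$tree))
  expect_equal(unname(pendant_lengths(res$tree)[c("A", "B2")]), c(3, 3))
  # bad rows are skipped, not fatal; counts conserved
  ins2 <- rbind(ins, data.frame(species = "B1", mode = "sister", anchor = "A",
                                pl_myr = 2, source = ""))
  res2 <- apply_grafts(bb, ins2)
  expect_equal(nrow(res2$report$grafted) + nrow(res2$report$skipped), nrow(ins2))
  expect_equal(ape::Ntip(res2$tree), 3 + nrow(res2$report$grafted))
  expect_match(res2$report$skipped$reason, "already in tree")
})

test_that("conflict rule sets both pendant lengths to anchor PL minus epsilon exactly", {
  for (s in 1:5) {
    tr <- simulate_bd_tree(0.25, 0, 40, seed = s + 30)
    sc <- make_graft_scenario(tr, k = 5, conflict_fraction = 1, seed = s + 60)
    state <- sc$backbone
    for (i in seq_len(nrow(sc$instructions))) {
      ins <- sc$instructions[i, ]
      p <- unname(pendant_lengths(state)[ins$anchor])
      res <- graft_tip(state, ins$species, ins$anchor, ins$pl_myr)
      state <- res$tree
      expect_identical(res$record$rule, "conflict_offset")
      pl <- pendant_lengths(state)
      expect_identical(unname(pl[ins$species]), p - 0.1)
      expect_identical(unname(pl[ins$anchor]), p - 0.1)
    }
  }
})

test_that("merging a tree with itself is the identity", {
  tr <- simulate_bd_tree(0.2, 0, 25, seed = 14)
  m <- merge_backbones(tr, tr)
  expect_true(topo_identical(m$tree, tr))
  expect_lt(max_age_error(m$tree, tr), 1e-9)
  expect_equal(nrow(m$report$grafted), 0)
})

test_that("shared node ages are averaged between the two backbones", {
  a <- read_newick(text = "((A:1,B:1):9,C:10);")
  b <- read_newick(text = "((A:3,B:3):9,C:12);")
  m <- merge_backbones(a, b)
  ages <- sort(unname(ape::branching.times(m$tree)))
  expect_equal(ages, c(2, 11))  # means of (1,3) and (10,12)
})

test_that("age averaging that inverts local order is repaired parent-up", {
  # cherry ages 5 in primary and 9.8 in secondary average to 7.4, above the
  # primary parent age of 7 -> parent raised to 7.4 + epsilon
  a <- read_newick(text = "(((A:5,B:5):2,C:7):3,D:10);")
  b <- read_newick(text = "(A:9.8,B:9.8);")
  m <- merge_backbones(a, b)
  ages <- node_ages(m$tree)
  cherry <- unname(ages[tree_mrca(m$tree, c("A", "B"))])
  parent <- unname(ages[tree_mrca(m$tree, c("A", "C"))])
  expect_equal(cherry, (5 + 9.8) / 2)
  expect_equal(parent, cherry + 0.1)
  expect_true(assert_ultrametric(m$tree))
})

test_that("secondary-only taxa are grafted back to their true positions", {
  for (s in 1:5) {
    tr <- simulate_bd_tree(0.2, 0, 50, seed = s + 20)
    sc <- make_graft_scenario(tr, k = 3, conflict_fraction = 0, seed = s + 40)
    extra <- sc$instructions$species
    anchors <- sc$instructions$anchor
    pool <- setdiff(sc$backbone$tip.label, anchors)
    set.seed(s)
    keep_shared <- union(anchors, sample(pool, 25))
    secondary <- prune_tips(tr, setdiff(tr$tip.label, c(keep_shared, extra)))
    m <- merge_backbones(sc$backbone, secondary)
    expect_true(topo_identical(m$tree, tr))
    expect_lt(max_age_error(m$tree, tr), 1e-9)
  }
})

test_that("merging requires at least two shared taxa", {
  a <- read_newick(text = "((A:1,B:1):1,C:2);")
  b <- read_newick(text = "((X:1,Y:1):1,C:2);")
  expect_error(merge_backbones(a, b), "fewer than 2")
})

test_that("instruction tables round-trip through delimited text", {
  ins <- data.frame(species = c("X_a", "Y_b"), mode = c("sister", "genus_base"),
                    anchor = c("A_c", "Y"), pl_myr = c(2.5, NA), source = "demo")
  f <- tempfile(fileext = ".tsv")
  write_graft_table(ins, f)
  back <- read_graft_table(f)
  expect_equal(back$species, ins$species)
  expect_equal(back$pl_myr, ins$pl_myr)
  expect_error(read_graft_table(write_fasta(matrix("a", 1, 1,
    dimnames = list("t", NULL)), tempfile())), "columns")
})
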