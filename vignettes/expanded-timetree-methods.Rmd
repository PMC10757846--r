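---
title: "Assembling and auditing expanded timetrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and auditing expanded timetrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timegraft)
```

## The problem

A clade's molecular divergence-time evidence is usually scattered: a large
synthetic backbone timetree covers most species, a phylogenomic study covers
fewer species but with better data, small published chronograms contain a
species or two each, some studies publish only undated gene trees, and some
species exist only as a handful of GenBank sequences. `timegraft` assembles
these into one clade-complete chronogram (an *expanded timetree*) and audits
the result against alternatives such as trees completed by dataless
imputation. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## Tree model and I/O

Trees are `ape::phylo` objects. A timetree is rooted and ultrametric with
branch lengths in millions of years (myr); every node has an age (tips at
0, root at the crown age) and a branch's length is the age difference
between its ends. Input Newick may contain polytomies and small rounding
noise; assembly *output* is guaranteed binary and exactly ultrametric.

Two numerical choices matter here:

* **Ultrametricity tolerance.** Hand-digitised published trees carry limited
  precision, so `read_newick(timed = TRUE)` accepts root-to-tip depth spread
  up to 1e-4 of the root age and then rebuilds every node age as the mean
  path length from the node to its descendant tips. Noise is averaged once
  at input rather than propagated through grafting arithmetic. Larger
  deviations are rejected, naming the most discordant tip pair.
* **Serialisation.** `write_newick` prints branch lengths at a fixed six
  decimals (sub-year precision on a myr scale). All precision-critical
  manipulation — grafting, pruning, merging — operates on the double-precision
  edge table directly and never round-trips through text; this is why the
  prune–regraft identity below holds to 1e-9 myr rather than to print
  precision. A consequence is that a single-tip tree, which `ape` cannot
  represent, is rejected by `write_newick` rather than serialised under a
  special convention.

## Grafting and the conflict rule

A graft instruction is (species, sister anchor, pendant length `pl`).
Attachment subdivides the anchor's terminal branch at age `pl`, so all
pre-existing divergence times are untouched — grafting only ever splits a
terminal (or, for genus placements, stem) branch. Two rules need care:

* **Conflict offset.** If `pl` is not younger than the anchor's own pendant
  length `p`, the requested attachment would collide with (or pass) the
  anchor's parent node. Both species are then attached at age `p − ε`, with
  ε = 0.1 myr by default. Subtracting ε (rather than adding) is the only
  direction that both avoids the polytomy and keeps the tree ultrametric;
  the concession is deliberately toward the backbone's own divergence. If
  `p ≤ ε` the instruction is skipped and reported rather than creating a
  nonpositive branch.
* **Genus-base placement.** When no consensus sister exists, the species is
  attached on the stem branch of its genus (tips sharing the label's first
  underscore-delimited token). The attachment age — the midpoint of the
  genus crown and stem ages — is a documented default, not a published
  convention: nothing in the source material fixes the age, and the midpoint
  is the unbiased choice within the feasible interval. It is isolated behind
  `assembly_config` so sensitivity to it can be tested.

Instructions are applied strictly in input order and failures skip rather
than abort, so one bad row cannot poison a long table. Later instructions
may anchor on species grafted earlier; the file-level wrapper additionally
sorts instructions sharing an anchor by decreasing pendant length, which
makes nested placements deterministic regardless of table order.

## Merging two backbones

`merge_backbones` keeps the primary topology and averages the ages of
matched nodes. Matching restricts each clade to the shared taxon set, so
taxa unique to one tree never block a match; a primary node is matched only
if it is the MRCA of its restricted clade and the secondary MRCA of the same
set restricts back to it. Averaging can locally invert age order (a child
averaged older than its unmatched parent); the repair raises the parent to
the child age plus ε, chosen to preserve the averaged tipward ages, which
dominate every downstream comparison. Taxa present only in the secondary
tree are converted to sister/PL instructions (sister = the shared tip with
the youngest common ancestor in the secondary tree) and grafted. Weighted
averaging across more than two sources and topological conflict resolution
are out of scope: the primary always wins on topology.

## Secondary calibration

Undated trees are scaled by relative node depths, computed as mean
root-to-tip path lengths (with a bottom-up pass enforcing monotonicity along
root-to-tip paths). This is deliberately simpler than relative-rate
frameworks used by dating software: on a strict-clock tree mean path depths
are exactly proportional to true ages, which anchors the closed-loop tests,
and the module is isolated so a relative-rate implementation can be swapped
in. Uniform `[min, max]` calibrations are summarised by their midpoints: one
constraint fixes the global scale directly; several constraints give the
least-squares scale through the origin. A calibrated node left outside its
range is clamped to the nearest bound through a global monotone
piecewise-linear remap of all ages (proportional below the node, linear
between it and the root), which cannot create negative branches; passes
repeat until every constraint holds to within 1e-9 of its bounds. Midpoint
scaling treats the range as a point summary, not a probability density;
full Bayesian calibration is out of scope.

The sequence prong uses the 50% per-site coverage filter, Jukes–Cantor
distances with pairwise deletion (matching the per-site filter philosophy),
and neighbor joining. Negative NJ branches are clamped to zero with the
deficit pushed to adjacent branches. Saturated pairs (proportion of
differences ≥ 0.75) are an error rather than a silent `NaN`. Model choice
stops at JC by design: the prong exists to place a handful of species with
one or two genes, not to compete with ML inference.

## Audit metrics

* **Equal splits.** `EI(tip)` halves each branch's contribution at every
  bifurcation between the branch and the tip, so ΣEI equals total tree
  length on binary trees — a conservation law the tests check to 1e-9 and
  that also pins the implementation against an independent brute-force
  path enumeration and against `picante`. Normalised EI divides by the
  crown age, making distributions comparable between trees dated under
  different calibration schemes. Polytomies are rejected by node number:
  assembly output is binary by construction, and silently resolving a
  user-supplied polytomy would change EI.
* **Regressions.** Shared-node ages use the same restricted-clade matching
  as merging. OLS is fitted y-on-x with x = the first (reference) tree;
  because that orientation is a convention, the reverse fit is always
  carried in the result. Pendant-length comparisons optionally scale by
  each tree's own crown age, which makes them invariant to global
  rescaling of either tree.
* **EI distribution comparison.** Distributions are summarised by deciles
  plus per-species paired differences when tip sets overlap; a
  visual-inspection comparison has no canonical statistic, and deciles keep
  the summary plain-text diffable.

## Diversification

The constant-rate birth–death fit maximises the reconstructed-process
likelihood of branching times, conditioned on the crown age and on both
crown lineages surviving, with uniform sampling fraction ρ (sampled extant
species / assumed total). At ρ = 1 the likelihood is algebraically identical
to the classic conditioned form, and the fit agrees with `ape::birthdeath`
to 1e-6 in log-likelihood — that agreement is a test, not the
implementation. Optimisation is over log net diversification and logit
turnover from a deterministic 3×3 grid of starts (grid rather than random
restarts: the surface is smooth in these coordinates and determinism keeps
every run reproducible without seed plumbing). A constant-rate fit plus LTT
inspection is the deliberate scope: episodic models, mass-extinction
detection and Bayes-factor comparisons belong to external samplers, and the
terminal-artifact mask exists precisely so the youngest window — biased by
uncataloged diversity — can be excluded from rate summaries without deleting
data.

## Synthetic data: what it emulates and what it does not

The generator provides the study conditions for every test:

* **Birth–death trees** conditioned on tip count (defaults used across the
  tests: λ ≈ 0.2–0.3, μ ≈ 0–0.1 per lineage per myr, 25–200 tips — the
  magnitudes typical of mammalian clade studies; the acceptance checks use
  50–200 tips).
* **Prune–regraft scenarios**: k tips are pruned sequentially, each chosen
  among tips whose *current* sister is a single tip, and instructions are
  emitted in reverse prune order. This makes zero-conflict scenarios exactly
  invertible — the headline oracle. The restriction is substantive: a tip
  whose sister clade holds several surviving tips attaches on that clade's
  stem, which no sister+PL instruction can express, so such tips are never
  selected (the generator's re-draw rule). Real curation faces exactly this
  ambiguity, which is why the genus-base mode exists.
* **Forced conflicts** inflate an instruction's PL to 1.5× the anchor's
  pendant length in the tree state the instruction will actually meet
  (determined by replay), guaranteeing the offset rule fires.
* **Rate variation** is i.i.d. lognormal per branch with mean 1; σ = 0.1 is
  the noise level for dating-recovery checks, σ = 0 the strict-clock limit
  for exactness checks.
* **Alignments** evolve under JC with uniformly scattered gaps.

What passing these tests shows: the pipeline's bookkeeping is exact, its
rules match their definitions, and its estimators recover truth under their
own generating models. What they do not show: robustness to topological
error in source trees, non-lognormal or autocorrelated rate variation,
non-uniform taxon sampling, or curation mistakes in real instruction tables
— none of which the generator emulates.

## Known limitations

* Node-age averaging covers exactly two backbones; multi-source weighted
  averaging is not implemented.
* Midpoint calibration ignores the width of uniform ranges except through
  clamping.
* The ε-repair after age averaging (parent := child + ε) is a local fix; a
  pathological secondary tree could chain several repairs.
* Equal-splits requires binary trees by design.
* The reference checks for a published expanded timetree
  (`validate_reference_tree`) require that tree's Newick file, which is not
  bundled; the corresponding acceptance test reports a failure until the
  file is supplied at `inst/extdata/ett_supplementary.nwk`.

## Problem sizes used by the test suite

Unit tests run on trees of 3–100 tips; the end-to-end identity check runs
100 scenarios of 50–200 tips with 5–20 grafts each; dating and
diversification recovery use 20 replicates each (40-tip trees at σ = 0.1,
200-tip Yule trees at λ = 0.2). The full suite completes in well under a
minute on one core.
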