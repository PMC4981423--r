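---
title: "Correcting gene trees by duplication-loss aware polytomy resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting gene trees by duplication-loss aware polytomy resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profnj)
```

## The problem

A gene tree estimated from a multiple alignment carries branch supports
(aLRT values in [0,1] or bootstrap percentages), and its weakly supported
branches are often wrong in ways that inflate the duplication-loss history
implied by reconciliation with the species phylogeny. `profnj` treats the
well-supported part of the tree as fixed, deletes everything below a support
threshold, and rebuilds the resulting polytomies so that (i) the total
weighted number of duplications and losses against a rooted binary species
tree is minimal among all trees containing the supported branches, and (ii)
among the cost-optimal rebuilds, joins follow the Neighbor-Joining (NJ)
criterion on a gene-to-gene distance matrix. The procedure is deterministic:
no tree-space search, no likelihood computation. Likelihood-based ranking of
the returned candidates is an explicit external hook (the outputs are
written in preference order for downstream ML tools).

## Model and procedure

**Reconciliation.** Each gene-tree node is mapped to the lowest common
ancestor (LCA) in the species tree of its descendants' species. An internal
node is a *duplication* iff it maps to the same species node as one of its
children; otherwise it is a speciation. Losses are counted by subdividing
each gene-tree edge along the species path between its endpoints: each
bypassed sibling subtree records one loss on its stem branch. The
reconciliation cost is `c_D · #duplications + c_L · #losses`
(`cost_scheme()`; both weights finite, nonnegative, not both zero).

**Polytomy DP.** For one polytomy, `m(s)` counts children whose root maps
exactly to species node `s`. `M(s, k)` is the optimal cost of the part of
the polytomy inside the subtree of `s` given `k` lineages entering `s`. Leaf
rows charge `m−k` duplications or `k−m` losses; internal rows minimize over
the copy number `v` at the bottom of the branch: `Δ(k,v)` events on the
branch plus both children evaluated at `v − m(s)` (the `m(s)` children
rooted at `s` stop there; the rest speciate). The polytomy's optimum is
`M(root, 1)`, where the root of the table is the LCA of the children's
species. Backtracking enumerates all optimal *count vectors* `V` (lineages
entering each species node), smallest `v` first, depth-first, so `--slimit`
truncation is deterministic.

**NJ realization.** A count vector is realized bottom-up: at each internal
species node, `V` speciation joins pair genes of the two child species; then
surplus genes are joined as duplications; missing genes are inserted as
*loss stubs* with infinite distance to everything. Pairs minimize
`Q(x,y) = (n−2)D(x,y) − Σ_t D(x,t) − Σ_t D(y,t)`; after a join the new
node's distances follow the usual NJ reduction, and a loss stub's partner
simply bequeaths its distances. Stubs are stripped from the user-facing
trees (`keep_losses = FALSE`) after being counted.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `threshold` | contract branches with support strictly below it (unitless, [0,1]) | 0.95 | the conventional aLRT cutoff for production runs; ties are kept |
| `cost_scheme(dup, loss)` | event weights (events) | (1, 1) | unweighted parsimony; `(1, 0.99999)` breaks ties toward losses as in large database runs |
| `slimit` | count vectors explored per polytomy | 1 | one optimal scenario; raise to explore the optimum's multiplicity |
| `plimit` | resolutions kept per rooting | 1 | combined with `slimit` caps the product over polytomies |
| `root_mode` | `best`/`all`/`none` | best | unrooted inputs are rooted on the branch minimizing the final cost |

Missing supports are treated as support 1 (kept): an unannotated branch is
usually a trivial or externally fixed one; `missing = "contract"` inverts
this.

## Design choices where the design was open

* **Scope of the Q sums.** The candidate pool for `Q` is the local one —
  the union of the two species' gene sets during speciation joins, or the
  single species' set during duplication joins — and `n` is that pool's
  size. This is the choice under which a single-species star collapses
  *exactly* to classical NJ (verified against `ape::nj` in the tests). Loss
  stubs never enter the sums (their infinite rows would poison every pair);
  they are consumed only when a speciation join has no real partner left.
* **Tie-breaking.** Argmin-Q ties go to the lexicographically smallest pair
  of insertion indices; equal-cost rootings are ordered by postorder of the
  rooted branch; equal-cost outputs keep generation order. All purely for
  determinism; none of these rules is claimed to match the original tool.
* **Rooting is on branches**, subdividing the chosen branch, one candidate
  per branch (2n−3 for a binary tree) — node-rooting is a special case and
  branch-rooting is standard practice.
* **Feasibility of k = 0.** A species subtree containing no polytomy
  children may receive zero lineages at zero cost. A subtree that does
  contain children must receive at least one (`M(s,0) = ∞` there): allowing
  the leaf-row formula at `k = 0` would price "creating" genes from no
  lineage, and measurably undercuts the true optimum (it loses against the
  brute-force oracle even at unit costs). This is the one place the
  implementation sharpens the row formulas stated for the table type.
* **Copy-number bound.** `K` defaults to the number of polytomy children
  plus one; no optimal solution needs more simultaneous lineages than
  leaves when both costs are positive. Backtracking errors out if an
  optimal path ever touches `K` (which can only happen with a zero loss
  cost, where the optimum set is unbounded anyway).
* **Distance rows for pre-resolved subtrees.** A supported binary clade
  entering a polytomy needs a distance row: it is the leaf-count-weighted
  mean of its leaves' rows (mean linkage), computed bottom-up. Subtrees
  produced by resolving a deeper polytomy instead carry the row produced by
  the successive NJ reductions — all polytomies of a tree share one
  evolving metric space, so later polytomies see reduced rows of earlier
  resolutions.
* **Mixed events on one branch.** `Δ(k,v)` never mixes duplications and
  losses on a single species branch; with both costs positive a mixed
  schedule is dominated by the pure one.

## Numerical conventions

Supports parse from internal Newick labels: values in [0,1] as-is, values
in (1,100] divided by 100. Distance matrices are square PHYLIP with relaxed
labels; asymmetries up to 1e-6 are averaged, larger ones are errors; `Inf`
entries are legal (loss stubs use them internally). DP cell comparisons in
backtracking use a 1e-9 tolerance (relevant for near-tied schemes like
(1, 0.99999)). Degenerate inputs: an already binary tree bypasses the DP
entirely (pure reconciliation); a polytomy whose children all belong to one
species leaf has a one-row table.

## What the simulator emulates — and what a green test does not establish

`simulate_gene_family()` runs a birth-death process along every species
branch (unit length): exponential waiting times, duplication probability
`r_D/(r_D+r_L)` per event. Defaults `r_D = r_L = 0.05` give on the order of
one or two visible events per family on a 16-leaf tree, with the 2×/4× rate
regimes used in the tests emulating elevated-rate families; the base rates
are a package choice, stated once, not fitted. Distances are exact path
lengths under exponentially drawn branch lengths, optionally perturbed by
truncated Gaussian noise; supports are planted (weak branches < 0.5, strong
0.99).

Two ground-truth records are kept. The *raw* record counts the generating
events; the *visible* record counts what survives pruning of extinct
lineages, computed by an independent leaf-set-containment pass. Parsimony
on a true tree can only recover the visible record — a duplication whose
one copy went fully extinct is indistinguishable from no event. Closure
tests assert `reconcile(true tree) == visible record` exactly.

The generator does not emulate: sequence-level evolution (distances come
from the true tree, not from alignments), rate variation across branches,
gene conversion or incomplete lineage sorting, and alignment/annotation
artifacts. A green correction test therefore establishes that the method
recovers topologies degraded by *support loss* under a well-specified
duplication-loss process with informative distances — not that it resolves
real families whose distance matrices are saturated or whose histories
violate the duplication-loss model.

## Known limitations

* Species trees must be rooted, binary and duplicate-free; transfers and
  non-LCA reconciliations are out of scope.
* Branch lengths are not estimated on corrected trees; only topology (and
  supports carried over on surviving branches) is the contract.
* The DP is the naive `O(|S|·K²)` construction per polytomy — appropriate
  at desk scale and anchored to an exhaustive oracle, not the linear-time
  construction known for unit costs.
* With `slimit`/`plimit` above 1 the combination of vectors across
  polytomies is explored depth-first and capped, so the retained subset,
  while deterministic, is an arbitrary prefix of the full optimum set.
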