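# profnj

Gene trees inferred from sequence alignments alone routinely contain weakly
supported branches, and reconciling such trees with a species tree inflates
inferred duplication and loss counts and distorts ancestral gene contents.
`profnj` corrects a gene tree deterministically, without tree-space search:
it contracts branches whose support falls below a threshold, resolves each
resulting polytomy at minimum weighted duplication–loss reconciliation cost
against a rooted binary species tree, and breaks ties among the cost-optimal
resolutions with the Neighbor-Joining criterion applied to a sequence
distance matrix. It is aimed at phylogenomics users who need corrected gene
trees, per-branch duplication/loss tallies and ancestral gene contents at
database scale.

## Method

Given a species tree *S*, a polytomy *P*, and *m(s)* = number of children of
*P* whose root maps to species node *s*, a dynamic program computes

    M(s, k) = optimal cost of resolving the part of P below s
              with k gene lineages entering s,

with, for a leaf *s*,

    M(s, k) = c_D (m(s) − k)   if k ≤ m(s)      (duplications)
            = c_L (k − m(s))   otherwise        (losses)

and, for an internal *s* with children *s1*, *s2*,

    M(s, k) = min over v ≥ m(s) of  Δ(k, v) + M(s1, v − m(s)) + M(s2, v − m(s)),

where Δ charges *v − k* duplications or *k − v* losses. The optimal cost of
the polytomy is `M(root, 1)`. Backtracking yields *count vectors* V — the
number of lineages entering each species node in some optimal resolution
(sibling nodes always receive equal counts; the root receives one).

A count vector is then realized bottom-up over *S*: speciation joins pair
genes from the two child species, surplus genes are joined as duplications,
missing genes become loss stubs at infinite distance. Each join picks the
pair minimizing the NJ criterion

    Q(x, y) = (n − 2) D(x, y) − Σ_t D(x, t) − Σ_t D(y, t)

over the current candidate pool, and distances are reduced by
`D(r, t) = (D(x, t) + D(y, t) − D(x, y)) / 2` (a loss partner's distances
are copied from the real partner). Degenerate inputs recover classical
tools: a binary input makes the pipeline a plain LCA reconciliation; a star
tree makes it a Wagner-parsimony ancestral gene content solver; a
single-species star returns the classical NJ tree.

## Worked example

```r
library(profnj)
S <- parse_newick("((a,b),c);", "species")
G <- parse_newick("((a1,b1)0.99,((a2,b2)0.30,c1)0.20);", "gene")
true <- parse_newick("((a1,b1),((a2,b2),c1));", "gene")
D <- simulate_distances(true, noise_sd = 0.1, seed = 42)
res <- correct_tree(G, S, D, threshold = 0.95, root_mode = "none",
                    map_rule = "prefix")
res
#> Corrected gene trees: 1 solution(s)
#>   rank cost duplications losses rooting
#> 1    1    1            1      0       1
write_newick(res$trees[[1]])
#> [1] "(((a1,b1)0.99,(a2,b2)),c1);"
```

The branch separating `(a2,b2)` from `c1` had support 0.30 and was
contracted together with the 0.20 branch; the resolver rebuilt the region so
that the two (a,b) cherries sit together, which costs a single ancient
duplication and no losses (cost 1). The original arrangement would have
needed one duplication plus one loss (cost 2). Supported branches (`(a1,b1)`,
0.99) are guaranteed to survive. Per-branch totals for downstream
genome-wide summaries:

```r
rec <- reconcile(res$trees[[1]], S, bind_species(res$trees[[1]], S, "prefix"))
branch_tally(list(rec), S)
#>   species duplications losses
#> 1    anc1            0      0
#> 2    anc2            1      0
#> 3       a            0      0
#> 4       b            0      0
#> 5       c            0      0
```

The DP table reproduces the textbook cells for a polytomy of three genes of
one species under unit costs:

```r
tab <- build_table(S, multiplicity(c("b","b","b"), S))
tab$M[match("b", S$label), c(2, 5)]   # k = 1 and k = 4
#> [1] 2 1
```

## Command line

```sh
Rscript exec/profnj -s species.nw -g gene.nw -d gene.dist -o out.nw \
    -n -r best -c nj --slimit 1 --plimit 1 --firstbest --cost 1 0.99999
```

writes the corrected trees (one Newick per line), `out.nw.report.tsv`
(cost, duplications, losses per solution) and `out.nw.log`.

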