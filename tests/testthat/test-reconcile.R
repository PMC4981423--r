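test_that("cherries map and annotate as the definitions force", {
  S <- fig_species()
  G <- parse_newick("(b1,b2);", "gene")
  r <- reconcile(G, S, bind_species(G, S, "prefix"))
  expect_equal(S$label[r$map_idx[1]], "b")
  expect_equal(r$events[1], "duplication")
  expect_equal(r$n_dup, 1L)

  G2 <- parse_newick("(a1,c1);", "gene")
  r2 <- reconcile(G2, S, bind_species(G2, S, "prefix"))
  expect_equal(r2$map_idx[1], S$root)
  expect_equal(r2$events[1], "speciation")

  G3 <- parse_newick("((b1,b2),b3);", "gene")
  r3 <- reconcile(G3, S, bind_species(G3, S, "prefix"))
  expect_equal(sum(r3$events == "duplication"), 2L)

  G4 <- parse_newick("(a1,b1);", "gene")
  r4 <- reconcile(G4, S, bind_species(G4, S, "prefix"))
  expect_equal(r4$events[1], "speciation")
})

test_that("congruent trees reconcile with zero events and unit content", {
  for (i in 1:10) {
    S <- simulate_species_tree(sample(3:8, 1), seed = 40 + i)
    fam <- simulate_gene_family(S, 0, 0, seed = i)
    r <- reconcile(fam$tree, S, fam$map)
    expect_equal(r$n_dup, 0L)
    expect_equal(r$n_loss, 0L)
    expect_true(all(r$content == 1L))
  }
})

test_that("missing genes in a leaf species cost one loss per entering lineage", {
  S <- fig_species()
  # two lineages pass the (a,b) ancestor but b has no genes
  G <- parse_newick("((a1,a2),(a3,c1));", "gene")
  r <- reconcile(G, S, bind_species(G, S, "prefix"))
  b <- match("b", S$label)
  expect_equal(r$loss_at[b], 2L)
})

test_that("lca_map agrees with the quadratic leaf-set oracle", {
  for (i in 1:60) {
    S <- simulate_species_tree(sample(3:9, 1), seed = 300 + i)
    fam <- simulate_gene_family(S, 0.25, 0.2, seed = 600 + i, min_leaves = 3)
    lm <- lca_map(fam$tree, S, fam$map)
    oracle <- lca_leafset_oracle(fam$tree, S, fam$map)
    # oracle visits in preorder; flatten_tree ids are preorder too
    for (k in seq_along(oracle)) {
      expect_equal(lm$map_idx[k], oracle[[k]]$m)
    }
  }
})

test_that("cost is invariant under child-order permutation", {
  permute <- function(node, seed) {
    profnj:::with_seed(seed, {
      shuffle <- function(n) {
        if (profnj:::is_leaf(n)) return(n)
        n$children <- lapply(sample(n$children), shuffle)
        n
      }
      shuffle(node)
    })
  }
  for (i in 1:15) {
    S <- simulate_species_tree(6, seed = 70 + i)
    fam <- simulate_gene_family(S, 0.3, 0.25, seed = 700 + i, min_leaves = 3)
    r1 <- reconcile(fam$tree, S, fam$map)
    r2 <- reconcile(permute(fam$tree, i), S, fam$map)
    expect_equal(r2$cost, r1$cost)
    expect_equal(r2$n_dup, r1$n_dup)
    expect_equal(sort(r2$loss_at), sort(r1$loss_at))
  }
})

test_that("per-branch losses satisfy the lineage bookkeeping identity", {
  # lineages at the bottom of an internal species branch all speciate:
  # losses charged to a child = (content + dups at the parent) - content(child)
  for (i in 1:25) {
    S <- simulate_species_tree(sample(3:8, 1), seed = 500 + i)
    fam <- simulate_gene_family(S, 0.3, 0.3, seed = 900 + i, min_leaves = 3)
    r <- reconcile(fam$tree, S, fam$map)
    origin <- r$map_idx[1]  # the identity holds below the family's origin
    for (p in which(!S$is_leaf)) {
      if (!profnj:::stree_is_ancestor(S, origin, p)) next
      bottom <- r$content[p] + r$dup_at[p]
      for (c in S$children[[p]]) {
        expect_equal(r$loss_at[c], bottom - r$content[c])
      }
    }
  }
})

test_that("reconciliation cost decomposes over the branch tallies", {
  cs <- cost_scheme(2, 0.5)
  S <- simulate_species_tree(6, seed = 21)
  recs <- lapply(1:8, function(i) {
    fam <- simulate_gene_family(S, 0.3, 0.3, seed = 50 + i, min_leaves = 3)
    reconcile(fam$tree, S, fam$map, cs)
  })
  for (r in recs) {
    expect_equal(r$cost, cs$dup * sum(r$dup_at) + cs$loss * sum(r$loss_at))
  }
  tally <- branch_tally(recs, S)
  expect_equal(tally$duplications, Reduce(`+`, lapply(recs, `[[`, "dup_at")))
  expect_equal(tally$losses, Reduce(`+`, lapply(recs, `[[`, "loss_at")))

  S2 <- simulate_species_tree(6, seed = 22)
  expect_error(branch_tally(recs[1], S2), "different species tree")
})

test_that("single-family tally places the event on the right branch", {
  S <- fig_species()
  G <- parse_newick("((b1,b2),c1);", "gene")
  r <- reconcile(G, S, bind_species(G, S, "prefix"))
  t <- branch_tally(list(r), S)
  expect_equal(t$duplications[t$species == "b"], 1L)
  expect_equal(sum(t$duplications), 1L)
  expect_equal(t$losses[t$species == "a"], 1L)  # (a,b) ancestor lineage lost in a
  expect_equal(sum(t$losses), 1L)
})
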