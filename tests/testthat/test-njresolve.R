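test_that("q_score reproduces the NJ selection on an additive quartet", {
  labs <- c("a", "b", "c", "d")
  tr <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);", "gene")
  D <- ape::cophenetic.phylo(profnj:::node_to_phylo(tr))[labs, labs]
  pool <- 1:4
  pairs <- t(combn(4, 2))
  qs <- apply(pairs, 1, function(p) q_score(D, pool, p[1], p[2]))
  best <- pairs[qs <= min(qs) + 1e-12, , drop = FALSE]
  keys <- apply(best, 1, paste, collapse = "-")
  expect_setequal(keys, c("1-2", "3-4"))

  # equidistant triple: all pairs tie
  De <- matrix(2, 3, 3); diag(De) <- 0
  q3 <- apply(t(combn(3, 2)), 1, function(p) q_score(De, 1:3, p[1], p[2]))
  expect_true(all(abs(q3 - q3[1]) < 1e-12))
})

test_that("the join reduction and the loss copy rule are exact", {
  S <- parse_newick("(a,b);", "species")
  D <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("x", "y", "t"), c("x", "y", "t")))
  V <- stats::setNames(c(1L, 1L, 1L), S$label)
  # x in a, y in b, t external
  r <- resolve_polytomy(S, list("x", "y"), c("a", "b"), V, D)
  expect_equal(r$extern_row, 4)  # (4 + 6 - 2) / 2
  expect_equal(r$joins, 1L)

  # y is a loss: distances copied from the real partner
  Dl <- matrix(c(0, 7), 1, 2, dimnames = list("x", c("x", "t")))
  Dl <- rbind(Dl, t = c(7, 0))
  V2 <- stats::setNames(c(1L, 1L, 1L), S$label)
  r2 <- resolve_polytomy(S, list("x"), c("a"), V2, Dl)
  expect_equal(r2$losses, 1L)
  expect_equal(r2$extern_row, 7)
  expect_equal(write_newick(prune_loss_stubs(r2$tree)), "x;")
})

test_that("coincident points keep their common distances after joining", {
  S <- parse_newick("(a,b);", "species")
  D <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("x", "y", "t"), c("x", "y", "t")))
  V <- stats::setNames(c(1L, 1L, 1L), S$label)
  r <- resolve_polytomy(S, list("x", "y"), c("a", "b"), V, D)
  expect_equal(r$extern_row, 5)
})

test_that("a single-species star resolves exactly like classical NJ", {
  S <- fig_species()
  for (i in 1:25) {
    n <- sample(4:9, 1)
    labs <- paste0("b", seq_len(n))
    D <- rand_dist(labs, seed = 40 + i)
    V <- stats::setNames(integer(S$n), S$label)
    V[match("b", S$label)] <- 1L
    res <- resolve_polytomy(S, as.list(labs), rep("b", n), V, D)
    nj <- ape::nj(D)
    expect_equal(rf_dist(res$tree, profnj:::phylo_to_node(nj)), 0)
    expect_equal(res$joins, n - 1L)
  }
})

test_that("three same-species genes with one entering lineage need two duplications", {
  S <- fig_species()
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("b1", "b2", "b3"), c("b1", "b2", "b3")))
  V <- stats::setNames(integer(S$n), S$label)
  V[match("b", S$label)] <- 1L
  r <- resolve_polytomy(S, as.list(c("b1", "b2", "b3")), rep("b", 3), V, D)
  expect_equal(r$joins, 2L)
  # closest pair joined first
  expect_equal(write_newick(r$tree), "(b3,(b1,b2));")
  rec <- reconcile(r$tree, S, c(b1 = "b", b2 = "b", b3 = "b"))
  expect_equal(rec$n_dup, 2L)
  expect_true(all(S$label[rec$map_idx[rec$events == "duplication"]] == "b"))
})

test_that("resolutions conserve the DP cost and realize the count vector", {
  for (i in 1:40) {
    inst <- rand_polytomy(i + 40, allow_internal = FALSE, max_children = 6)
    if (length(inst$sp) < 3) next
    labs <- paste0("x", seq_along(inst$sp))
    D <- rand_dist(labs, seed = 700 + i)
    tab <- build_table(inst$S, multiplicity(inst$sp, inst$S), inst$costs)
    vecs <- backtrack_count_vectors(tab, limit = 3)
    map <- stats::setNames(inst$sp, labs)
    for (V in vecs) {
      r <- resolve_polytomy(inst$S, as.list(labs), inst$sp, V, D)
      rec <- reconcile(r$tree, inst$S, map, inst$costs)
      expect_equal(rec$cost, optimal_cost(tab), tolerance = 1e-9)
      # with loss stubs retained, entering-lineage counts equal V
      lm <- lca_map(r$tree, inst$S, map)
      expect_equal(gene_content(lm, inst$S)[tab$sub], unname(V)[tab$sub])
      expect_equal(r$joins, n_leaves(r$tree) - 1L)
      # determinism
      r2 <- resolve_polytomy(inst$S, as.list(labs), inst$sp, V, D)
      expect_identical(write_newick(r2$tree), write_newick(r$tree))
    }
  }
})

test_that("loss stubs are pruned with unary suppression", {
  stub <- profnj:::g_leaf("b", loss = TRUE)
  t <- profnj:::g_node(list(profnj:::g_node(list(profnj:::g_leaf("x"), stub)),
                            profnj:::g_leaf("y")))
  p <- prune_loss_stubs(t)
  expect_equal(write_newick(p), "(x,y);")
  expect_null(prune_loss_stubs(stub))
})
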