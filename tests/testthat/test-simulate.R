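test_that("species tree simulation is reproducible and well formed", {
  s2 <- simulate_species_tree(2, seed = 1)
  expect_equal(sum(s2$is_leaf), 2L)
  s16 <- simulate_species_tree(16, seed = 5)
  expect_equal(sum(!s16$is_leaf), 15L)
  expect_identical(write_newick(simulate_species_tree(9, seed = 3)),
                   write_newick(simulate_species_tree(9, seed = 3)))
})

test_that("a zero-rate family is congruent with the species tree", {
  S <- simulate_species_tree(7, seed = 2)
  fam <- simulate_gene_family(S, 0, 0, seed = 4)
  expect_equal(n_leaves(fam$tree), 7L)
  expect_true(all(fam$census == 1L))
  expect_equal(fam$n_dup + fam$n_loss, 0L)
  relabel <- function(node) {
    if (profnj:::is_leaf(node)) node$label <- unname(fam$map[node$label])
    else node$children <- lapply(node$children, relabel)
    node
  }
  expect_equal(rf_dist(relabel(fam$tree), S), 0)
})

test_that("without losses the gene count never decreases along a path", {
  for (i in 1:10) {
    S <- simulate_species_tree(6, seed = 60 + i)
    fam <- simulate_gene_family(S, 0.4, 0, seed = 80 + i)
    expect_equal(sum(fam$raw_loss), 0L)
    expect_equal(sum(fam$loss_at), 0L)
    r <- reconcile(fam$tree, S, fam$map)
    for (s in seq_len(S$n)) {
      p <- S$parent[s]
      if (p > 0) expect_gte(r$content[s], r$content[p])
    }
  }
})

test_that("reconciling a true tree reproduces the recorded visible events", {
  for (i in 1:40) {
    S <- simulate_species_tree(sample(4:10, 1), seed = 400 + i)
    fam <- simulate_gene_family(S, 0.3, 0.25, seed = 800 + i, min_leaves = 3)
    r <- reconcile(fam$tree, S, fam$map)
    expect_equal(unname(r$dup_at), unname(fam$dup_at))
    expect_equal(unname(r$loss_at), unname(fam$loss_at))
  }
})

test_that("doubling the duplication rate doubles the expected raw count", {
  S <- simulate_species_tree(5, seed = 12)
  mean_dups <- function(rate, seeds) {
    mean(vapply(seeds, function(s) {
      sum(simulate_gene_family(S, rate, 0.05, seed = s, min_leaves = 1)$raw_dup)
    }, numeric(1)))
  }
  m1 <- mean_dups(0.05, 1:1000)
  m2 <- mean_dups(0.10, 2001:3000)
  expect_gt(m2 / m1, 1.6)
  expect_lt(m2 / m1, 2.5)
})

test_that("distances are additive at zero noise and reproducible", {
  S <- simulate_species_tree(6, seed = 31)
  fam <- simulate_gene_family(S, 0.2, 0.1, seed = 32, min_leaves = 4)
  D0 <- simulate_distances(fam$tree, noise_sd = 0, seed = 33)
  expect_identical(D0, simulate_distances(fam$tree, noise_sd = 0, seed = 33))
  expect_true(isSymmetric(D0))
  expect_true(all(diag(D0) == 0))
  # NJ consistency: the additive matrix returns the true unrooted topology
  nj <- profnj:::phylo_to_node(ape::nj(D0))
  expect_equal(rf_dist(nj, fam$tree), 0)
  # four-point condition on a few quadruples
  lv <- rownames(D0)
  if (length(lv) >= 4) {
    q <- lv[1:4]
    sums <- c(D0[q[1], q[2]] + D0[q[3], q[4]],
              D0[q[1], q[3]] + D0[q[2], q[4]],
              D0[q[1], q[4]] + D0[q[2], q[3]])
    expect_lt(sort(sums, decreasing = TRUE)[1] -
              sort(sums, decreasing = TRUE)[2], 1e-9)
  }
})

test_that("degraded supports contract to exactly the planted set", {
  S <- simulate_species_tree(8, seed = 41)
  fam <- simulate_gene_family(S, 0.3, 0.1, seed = 42, min_leaves = 6)
  nint <- degrade_supports(fam$tree, 0, seed = 1)$n_internal

  d0 <- degrade_supports(fam$tree, 0, seed = 43)$tree
  expect_equal(profnj:::n_internal(contract_low_support(d0, 0.95)),
               profnj:::n_internal(d0))

  dall <- degrade_supports(fam$tree, nint, seed = 44)$tree
  star <- contract_low_support(dall, 0.95)
  expect_equal(profnj:::n_internal(star), 1L)

  expect_error(degrade_supports(fam$tree, nint + 1L, seed = 1), "exceeds")
})

test_that("fixture bundles are written as plain text", {
  dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
  S <- simulate_species_tree(4, seed = 51)
  fams <- lapply(1:2, function(i) {
    f <- simulate_gene_family(S, 0.2, 0.1, seed = 60 + i, min_leaves = 2)
    f$dist <- simulate_distances(f$tree, noise_sd = 0, seed = 70 + i)
    f
  })
  manifest <- write_fixture_bundle(dir, S, fams)
  expect_true(file.exists(file.path(dir, "species.nw")))
  expect_true(file.exists(file.path(dir, "gene1.nw")))
  expect_true(file.exists(file.path(dir, "gene2.dist")))
  expect_true(file.exists(file.path(dir, "gene1.truth.tsv")))
  mf <- utils::read.table(manifest, header = TRUE, sep = "\t")
  expect_equal(nrow(mf), 2L)
  D <- read_distance_matrix(file = file.path(dir, "gene2.dist"))
  expect_lt(max(abs(D - fams[[2]]$dist)), 1e-9)
})
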