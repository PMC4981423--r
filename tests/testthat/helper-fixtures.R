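# Shared fixtures and small oracles, all built in code.

fig_species <- function() parse_newick("((a,b),c);", "species")

# random symmetric positive distance matrix over given labels
rand_dist <- function(labels, seed = NULL) {
  profnj:::with_seed(seed, {
    n <- length(labels)
    D <- matrix(stats::runif(n * n, 0.1, 3), n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    dimnames(D) <- list(labels, labels)
    D
  })
}

# unrooted Robinson-Foulds distance between two trees (nested nodes or
# stree), via phangorn on the ape conversion
rf_dist <- function(a, b) {
  pa <- ape::unroot(profnj:::node_to_phylo(if (inherits(a, "stree")) a$node else a))
  pb <- ape::unroot(profnj:::node_to_phylo(if (inherits(b, "stree")) b$node else b))
  phangorn::RF.dist(pa, pb)
}

# quadratic leaf-set LCA oracle: the image of a gene node is the deepest
# species node whose leaf set contains all species of the gene subtree
lca_leafset_oracle <- function(G, S, map) {
  leafsets <- lapply(seq_len(S$n), function(s) {
    ids <- profnj:::stree_subtree(S, s)
    S$label[ids[S$is_leaf[ids]]]
  })
  res <- list()
  walk <- function(node) {
    sps <- unique(unname(map[tree_leaves(node)]))
    cand <- which(vapply(leafsets, function(ls) all(sps %in% ls), logical(1)))
    m <- cand[which.max(S$depth[cand])]
    res[[length(res) + 1L]] <<- list(newick = write_newick(node), m = m)
    for (ch in node$children) walk(ch)
    m
  }
  walk(G)
  res
}

# draw a random polytomy instance: small species tree, child species
# (possibly internal nodes when allow_internal), a cost scheme
rand_polytomy <- function(i, max_species = 4, max_children = 6,
                          allow_internal = TRUE, schemes = NULL) {
  if (is.null(schemes)) {
    schemes <- list(cost_scheme(1, 1), cost_scheme(1, 0.99999), cost_scheme(2, 1))
  }
  S <- simulate_species_tree(sample(2:max_species, 1), seed = 10000 + i)
  pool <- if (allow_internal) S$label else S$label[S$is_leaf]
  nch <- sample(2:max_children, 1)
  sp <- sample(pool, nch, replace = TRUE)
  list(S = S, sp = sp, costs = schemes[[(i %% length(schemes)) + 1L]])
}
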