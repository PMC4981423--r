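# Synthetic fixture generator: species trees, birth-death gene families
# with recorded event placements, additive noisy distance matrices and
# support degradation.  Everything a correction run needs, with ground
# truth attached.

with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulate a rooted binary species tree
#'
#' Random topology by sequential joining of lineages; every branch gets
#' length 1 (the unit in which the birth-death rates are expressed).
#'
#' @param n_leaves number of species (>= 2); leaves are labelled `s1..sn`
#' @param seed RNG seed (restores the caller's RNG state)
#' @return an `stree`
#' @export
simulate_species_tree <- function(n_leaves, seed = NULL) {
  stopifnot(n_leaves >= 2)
  with_seed(seed, {
    pool <- lapply(seq_len(n_leaves), function(i) g_leaf(paste0("s", i), length = 1))
    while (length(pool) > 1) {
      ij <- sample.int(length(pool), 2)
      joined <- g_node(pool[ij], length = 1)
      pool <- c(pool[-ij], list(joined))
    }
    root <- pool[[1]]
    root$length <- NA_real_
    stree_build(root)
  })
}

#' Simulate a duplication-loss gene family along a species tree
#'
#' One gene lineage enters the root and evolves by a birth-death process
#' on every species branch (unit length): duplications split a lineage,
#' losses kill it.  Extinct families are redrawn.  Raw event counts (the
#' generating process) and visible event counts (what survives pruning of
#' extinct lineages, computed by an independent leaf-set LCA pass) are
#' both recorded; parsimonious reconciliation of the true tree can only
#' be expected to recover the visible counts.
#'
#' @param S species tree (`stree`), branch length 1 per branch
#' @param rate_dup duplication rate per unit branch length
#' @param rate_loss loss rate per unit branch length
#' @param seed RNG seed
#' @param min_leaves redraw until at least this many surviving genes
#' @param max_tries rejection limit
#' @return list with `tree` (true binary gene tree, leaves `g<i>_<sp>`),
#'   `map`, `census` (genes per species leaf), `raw_dup`, `raw_loss`,
#'   `dup_at`, `loss_at` (visible counts per species node), `n_dup`,
#'   `n_loss`
#' @export
simulate_gene_family <- function(S, rate_dup = 0.05, rate_loss = 0.05,
                                 seed = NULL, min_leaves = 2L,
                                 max_tries = 200L) {
  stopifnot(rate_dup >= 0, rate_loss >= 0)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      raw_dup <- integer(S$n); raw_loss <- integer(S$n)
      total <- rate_dup + rate_loss
      nlin <- 0L
      overflow <- FALSE
      arrive <- function(s) {
        if (S$is_leaf[s]) return(g_leaf(S$label[s]))
        ch <- S$children[[s]]
        a <- lineage(ch[1], 1)
        b <- lineage(ch[2], 1)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        g_node(list(a, b))
      }
      lineage <- function(s, tleft) {
        nlin <<- nlin + 1L
        if (nlin > 20000L) { overflow <<- TRUE; return(NULL) }
        if (total > 0) {
          w <- stats::rexp(1, total)
          if (w < tleft) {
            if (stats::runif(1) < rate_dup / total) {
              raw_dup[s] <<- raw_dup[s] + 1L
              a <- lineage(s, tleft - w)
              b <- lineage(s, tleft - w)
              if (is.null(a) && is.null(b)) return(NULL)
              if (is.null(a)) return(b)
              if (is.null(b)) return(a)
              return(g_node(list(a, b)))
            } else {
              raw_loss[s] <<- raw_loss[s] + 1L
              return(NULL)
            }
          }
        }
        arrive(s)
      }
      tree <- arrive(S$root)
      if (overflow || is.null(tree)) next
      nl <- n_leaves(tree)
      if (nl < min_leaves) next
      # name leaves g<i>_<species>, left to right
      counter <- 0L
      name_leaves <- function(node) {
        if (is_leaf(node)) {
          counter <<- counter + 1L
          node$label <- paste0("g", counter, "_", node$label)
          return(node)
        }
        node$children <- lapply(node$children, name_leaves)
        node
      }
      tree <- name_leaves(tree)
      lv <- tree_leaves(tree)
      map <- stats::setNames(sub(".*_", "", lv), lv)
      vis <- truth_events(tree, map, S)
      census <- table(factor(unname(map), levels = S$label[S$is_leaf]))
      return(list(tree = as_gtree(tree), map = map,
                  census = stats::setNames(as.integer(census), names(census)),
                  raw_dup = stats::setNames(raw_dup, S$label),
                  raw_loss = stats::setNames(raw_loss, S$label),
                  dup_at = vis$dup_at, loss_at = vis$loss_at,
                  n_dup = sum(vis$dup_at), n_loss = sum(vis$loss_at)))
    }
    stop("no surviving family after ", max_tries, " draws; lower the loss rate")
  })
}

# Independent event annotation used as simulator ground truth: species
# assignment by leaf-set containment (not the reconcile module's
# depth-walk LCA), then the standard per-edge loss count.
truth_events <- function(tree, map, S) {
  leafsets <- vector("list", S$n)
  for (s in rev(stree_subtree(S, S$root))) {
    leafsets[[s]] <- if (S$is_leaf[s]) S$label[s]
                     else unlist(leafsets[S$children[[s]]])
  }
  assign_node <- function(spset) {
    v <- S$root
    repeat {
      if (S$is_leaf[v]) return(v)
      ch <- S$children[[v]]
      inl <- all(spset %in% leafsets[[ch[1]]])
      inr <- all(spset %in% leafsets[[ch[2]]])
      if (inl) v <- ch[1] else if (inr) v <- ch[2] else return(v)
    }
  }
  dup_at <- integer(S$n); loss_at <- integer(S$n)
  walk <- function(node) {
    if (is_leaf(node)) {
      return(list(m = assign_node(unname(map[node$label])),
                  set = unname(map[node$label])))
    }
    kids <- lapply(node$children, walk)
    set <- unique(unlist(lapply(kids, `[[`, "set")))
    m <- assign_node(set)
    isdup <- any(vapply(kids, function(k) k$m == m, logical(1)))
    if (isdup) dup_at[m] <<- dup_at[m] + 1L
    for (k in kids) {
      if (k$m != m) {
        path <- c(m, stree_path_between(S, m, k$m), k$m)
        from <- if (isdup) 1L else 2L
        if (length(path) >= from + 1L) {
          for (i in seq.int(from, length(path) - 1L)) {
            sib <- setdiff(S$children[[path[i]]], path[i + 1L])
            loss_at[sib] <<- loss_at[sib] + 1L
          }
        }
      }
    }
    list(m = m, set = set)
  }
  walk(tree)
  list(dup_at = stats::setNames(dup_at, S$label),
       loss_at = stats::setNames(loss_at, S$label))
}

#' Additive distance matrix from a gene tree, with optional noise
#'
#' Branch lengths are drawn (exponential with mean `mean_length`) unless
#' the tree already carries them and `lengths = "keep"`.  The matrix of
#' leaf-to-leaf path lengths is then perturbed by symmetric Gaussian
#' noise truncated so entries stay positive.
#'
#' @param G binary gene tree
#' @param noise_sd standard deviation of the additive noise (0 = exactly
#'   additive)
#' @param seed RNG seed
#' @param lengths `"draw"` or `"keep"`
#' @param mean_length mean of drawn branch lengths
#' @return symmetric distance matrix over the gene leaves
#' @export
simulate_distances <- function(G, noise_sd = 0, seed = NULL,
                               lengths = c("draw", "keep"), mean_length = 0.5) {
  lengths <- match.arg(lengths)
  with_seed(seed, {
    if (lengths == "draw") {
      redraw <- function(node, top) {
        node$length <- if (top) NA_real_ else stats::rexp(1, 1 / mean_length)
        node$children <- lapply(node$children, redraw, top = FALSE)
        node
      }
      G <- redraw(G, TRUE)
    }
    ph <- node_to_phylo(G)
    D <- ape::cophenetic.phylo(ph)
    lv <- rownames(D)
    if (noise_sd > 0) {
      E <- matrix(stats::rnorm(length(D), 0, noise_sd), nrow(D))
      E <- (E + t(E)) / 2
      D <- pmax(D + E, 1e-6)
    }
    diag(D) <- 0
    dimnames(D) <- list(lv, lv)
    D
  })
}

#' Plant weak supports on a gene tree
#'
#' Chooses `n_weak` internal non-root branches uniformly at random and
#' assigns them supports below 0.5; all other internal branches get
#' support 0.99.  Contracting at the default threshold 0.95 therefore
#' removes exactly the planted set.
#'
#' @param G binary gene tree
#' @param n_weak number of branches to weaken (at most the internal
#'   branch count)
#' @param seed RNG seed
#' @return list with `tree` (supports attached) and `n_internal` (number
#'   of internal non-root branches)
#' @export
degrade_supports <- function(G, n_weak, seed = NULL) {
  nint <- 0L
  count <- function(node, top) {
    if (is_leaf(node)) return(invisible(NULL))
    if (!top) nint <<- nint + 1L
    for (ch in node$children) count(ch, FALSE)
  }
  count(G, TRUE)
  if (n_weak > nint) stop("n_weak exceeds internal branch count (", nint, ")")
  with_seed(seed, {
    weak <- sample.int(nint, n_weak)
    idx <- 0L
    paint <- function(node, top) {
      if (is_leaf(node)) return(node)
      if (!top) {
        idx <<- idx + 1L
        node$support <- if (idx %in% weak) stats::runif(1, 0, 0.5) else 0.99
      } else {
        node$support <- NA_real_
      }
      node$children <- lapply(node$children, paint, top = FALSE)
      node
    }
    list(tree = as_gtree(paint(G, TRUE)), n_internal = nint)
  })
}

#' Write a self-contained fixture bundle
#'
#' Writes `species.nw` plus, per family, `gene<N>.nw` (true tree with
#' supports if present), `gene<N>.dist` and `gene<N>.truth.tsv`
#' (per-species visible event counts), and a `manifest.tsv`.
#'
#' @param dir output directory (created if needed)
#' @param S species tree
#' @param families list of outputs of [simulate_gene_family()], each
#'   optionally with an added `dist` matrix
#' @return the manifest path, invisibly
#' @export
write_fixture_bundle <- function(dir, S, families) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(S, file.path(dir, "species.nw"))
  rows <- list()
  for (i in seq_along(families)) {
    fam <- families[[i]]
    gpath <- file.path(dir, sprintf("gene%d.nw", i))
    write_newick(fam$tree, gpath)
    if (!is.null(fam$dist)) {
      write_distance_matrix(fam$dist, file.path(dir, sprintf("gene%d.dist", i)))
    }
    truth <- data.frame(species = S$label, duplications = unname(fam$dup_at),
                        losses = unname(fam$loss_at))
    utils::write.table(truth, file.path(dir, sprintf("gene%d.truth.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rows[[i]] <- data.frame(family = i, n_genes = n_leaves(fam$tree),
                            dups = fam$n_dup, losses = fam$n_loss)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
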