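# Dynamic program over the species tree for resolving one polytomy at
# minimum weighted duplication-loss cost.
#
# M(s, k) = cost of an optimal resolution of the part of the polytomy
# lying in the species subtree of s, given k gene lineages entering s
# (before any duplication in s).  m(s) children of the polytomy map
# exactly to s; at the bottom of branch s there are v lineages, of which
# m(s) are the roots of those children and v - m(s) speciate into both
# children of s.  Transforming k into v costs (v-k) duplications or
# (k-v) losses -- mixing the two on one branch is dominated when both
# costs are positive.

#' Leaf-branch cost of the polytomy DP
#'
#' Cost of reconciling `m_s` genes observed in a leaf species with `k`
#' lineages entering it: `m_s - k` duplications when `k <= m_s`, else
#' `k - m_s` losses.
#'
#' @param m_s number of polytomy children mapped to the leaf species
#' @param k number of lineages entering the species
#' @param costs a [cost_scheme()]
#' @return the weighted event cost
#' @examples
#' leaf_cost(3, 1) # two duplications
#' leaf_cost(3, 4) # one loss
#' @export
leaf_cost <- function(m_s, k, costs = cost_scheme()) {
  stopifnot(m_s >= 0, k >= 0)
  if (k <= m_s) costs$dup * (m_s - k) else costs$loss * (k - m_s)
}

delta_cost <- function(k, v, costs) {
  if (v >= k) costs$dup * (v - k) else costs$loss * (k - v)
}

#' Multiplicity vector of a polytomy
#'
#' Counts, per species node, the polytomy children whose root maps
#' exactly to that node.
#'
#' @param child_species character vector of species labels (one per child)
#' @param S species tree
#' @return integer vector of length `S$n`
#' @export
multiplicity <- function(child_species, S) {
  idx <- match(child_species, S$label)
  if (anyNA(idx)) {
    stop("unknown species: ", paste(child_species[is.na(idx)], collapse = ", "))
  }
  tabulate(idx, nbins = S$n)
}

#' Build the polytomy-resolution DP table
#'
#' Computes `M(s, k)` for every species node `s` in the subtree rooted at
#' the LCA of the children's species and every `k` in `0..K`.  A species
#' subtree that contains no polytomy children may receive zero lineages at
#' zero cost; subtrees that do contain children require at least one
#' entering lineage (`M(s, 0)` is infinite there).
#'
#' @param S species tree
#' @param mult integer multiplicity vector (see [multiplicity()])
#' @param costs a [cost_scheme()]
#' @param K copy-number bound; defaults to the number of polytomy
#'   children plus one (a resolution never needs more simultaneous
#'   lineages than leaves; the extra column is a boundary guard)
#' @param root species index to root the table at; defaults to the LCA of
#'   all species carrying children
#' @return object of class `dp_table`
#' @export
build_table <- function(S, mult, costs = cost_scheme(), K = NULL, root = NULL) {
  stopifnot(length(mult) == S$n, all(mult >= 0))
  total <- sum(mult)
  if (total < 1) stop("polytomy has no children")
  if (is.null(root)) root <- stree_lca(S, which(mult > 0))
  if (is.null(K)) K <- total + 1L
  if (K < total) stop("K must be at least the number of polytomy children (", total, ")")
  sub <- stree_subtree(S, root)
  below <- integer(S$n)
  for (s in rev(sub)) {
    below[s] <- mult[s] + sum(below[S$children[[s]]])
  }
  M <- matrix(Inf, nrow = S$n, ncol = K + 1L)  # columns are k = 0..K
  post <- intersect(S$postorder, sub)
  for (s in post) {
    M[s, 1L] <- if (below[s] == 0L) 0 else Inf
    if (S$is_leaf[s]) {
      for (k in seq_len(K)) M[s, k + 1L] <- leaf_cost(mult[s], k, costs)
    } else {
      ch <- S$children[[s]]
      for (k in seq_len(K)) {
        best <- Inf
        for (v in seq.int(mult[s], K)) {
          kk <- v - mult[s]
          cand <- delta_cost(k, v, costs) + M[ch[1], kk + 1L] + M[ch[2], kk + 1L]
          if (cand < best) best <- cand
        }
        M[s, k + 1L] <- best
      }
    }
  }
  structure(list(M = M, K = K, root = root, sub = sub, mult = mult,
                 below = below, costs = costs, S = S),
            class = "dp_table")
}

#' @export
print.dp_table <- function(x, ...) {
  cat("Polytomy DP table:", sum(x$mult), "children, rooted at species '",
      x$S$label[x$root], "', optimal cost ", optimal_cost(x), "\n", sep = "")
  invisible(x)
}

#' Optimal resolution cost of a polytomy
#'
#' The table entry at the root with a single entering lineage.
#'
#' @param table a `dp_table`
#' @return the minimal weighted duplication-loss cost
#' @export
optimal_cost <- function(table) {
  table$M[table$root, 2L]
}

#' Enumerate optimal count vectors by backtracking
#'
#' A count vector assigns to every species node the number of gene
#' lineages entering it in some cost-optimal resolution.  Sibling nodes
#' always receive equal counts and the root receives one lineage.
#' Vectors are enumerated depth-first, smallest copy number first, so the
#' order is deterministic and a truncation limit is meaningful.
#'
#' @param table a `dp_table`
#' @param limit maximum number of vectors to return (default all)
#' @return list of integer vectors of length `S$n` (zero outside the
#'   table's species subtree), each annotated with the species labels
#' @export
backtrack_count_vectors <- function(table, limit = Inf) {
  S <- table$S; M <- table$M; K <- table$K; costs <- table$costs
  tol <- 1e-9
  emitted <- 0L
  vecs_at <- function(s, k, cap) {
    base <- integer(S$n)
    if (k == 0L) {
      return(list(base))
    }
    base[s] <- k
    if (S$is_leaf[s]) return(list(base))
    ch <- S$children[[s]]
    target <- M[s, k + 1L]
    out <- list()
    for (v in seq.int(table$mult[s], K)) {
      kk <- v - table$mult[s]
      tot <- delta_cost(k, v, costs) + M[ch[1], kk + 1L] + M[ch[2], kk + 1L]
      if (is.finite(tot) && abs(tot - target) <= tol) {
        if (v == K) {
          stop("optimal backtrack touches the copy-number bound K = ", K,
               "; rebuild the table with a larger K")
        }
        lv <- vecs_at(ch[1], kk, cap)
        for (l in lv) {
          rv <- vecs_at(ch[2], kk, cap - length(out))
          for (r in rv) {
            out[[length(out) + 1L]] <- base + l + r
            if (length(out) >= cap) return(out)
          }
        }
      }
    }
    out
  }
  res <- vecs_at(table$root, 1L, if (is.finite(limit)) as.integer(limit) else .Machine$integer.max)
  lapply(res, function(v) stats::setNames(v, S$label))
}

# ---- brute-force oracle ------------------------------------------------

# cache of flattened rooted binary shapes, keyed by leaf count
.topo_cache <- new.env(parent = emptyenv())

# All rooted binary trees over leaves x1..xn (nested nodes).
all_rooted_topologies <- function(n) {
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  insert_everywhere <- function(node, leaf) {
    res <- list(g_node(list(node, leaf)))
    if (!is_leaf(node)) {
      for (j in seq_along(node$children)) {
        for (sub in insert_everywhere(node$children[[j]], leaf)) {
          nd <- node
          nd$children[[j]] <- sub
          res[[length(res) + 1L]] <- nd
        }
      }
    }
    res
  }
  trees <- list(g_leaf("x1"))
  if (n >= 2) {
    for (i in 2:n) {
      leaf <- g_leaf(paste0("x", i))
      trees <- unlist(lapply(trees, insert_everywhere, leaf = leaf),
                      recursive = FALSE)
    }
  }
  .topo_cache[[key]] <- trees
  trees
}

#' Exhaustively score all binary resolutions of a polytomy
#'
#' Test oracle: enumerates every rooted binary tree over the polytomy's
#' children ((2n-3)!! topologies) and scores each by LCA reconciliation.
#' Children may map to internal species nodes (pre-resolved subtrees).
#'
#' @param child_species character vector of species labels, one per child
#'   (children are named `x1..xn` in the returned trees)
#' @param S species tree
#' @param costs a [cost_scheme()]
#' @param max_children enumeration guard (default 8)
#' @return list with `min_cost`, `costs` (per topology), `trees` (all
#'   topologies), `optimal` (indices of optimal topologies), and
#'   `count_vectors` (entering-lineage count per species node, for each
#'   optimal topology: gene content plus losses charged to the node)
#' @export
brute_force_resolutions <- function(child_species, S, costs = cost_scheme(),
                                    max_children = 8L) {
  n <- length(child_species)
  if (n > max_children) stop("too many children for exhaustive enumeration: ", n)
  if (n < 2) stop("need at least 2 children")
  map <- stats::setNames(child_species, paste0("x", seq_len(n)))
  trees <- all_rooted_topologies(n)
  cost_of <- numeric(length(trees))
  lms <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    lm <- lca_map(trees[[i]], S, map)
    ev <- annotate_events(lm)
    loss_at <- count_losses(lm, S, ev)
    cost_of[i] <- costs$dup * sum(ev == "duplication") + costs$loss * sum(loss_at)
    lms[[i]] <- list(lm = lm, loss_at = loss_at)
  }
  mc <- min(cost_of)
  opt <- which(cost_of <= mc + 1e-9)
  cvs <- lapply(opt, function(i) {
    v <- gene_content(lms[[i]]$lm, S) + lms[[i]]$loss_at
    stats::setNames(v, S$label)
  })
  list(min_cost = mc, costs = cost_of, trees = trees, optimal = opt,
       count_vectors = cvs)
}
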