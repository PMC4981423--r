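# Internal tree representation
#
# Gene trees are nested lists of nodes; a node is
#   list(label, support, length, loss, children)
# where `children` is a (possibly empty) list of nodes.  Leaves have an
# empty children list and a non-NA label.  `loss = TRUE` marks artificial
# loss stubs inserted during polytomy resolution.  Species trees are kept
# in an indexed form (class "stree") because reconciliation needs constant
# parent/depth/LCA lookups.

g_leaf <- function(label, length = NA_real_, loss = FALSE) {
  list(label = label, support = NA_real_, length = length,
       loss = loss, children = list())
}

g_node <- function(children, label = NA_character_, support = NA_real_,
                   length = NA_real_) {
  stopifnot(is.list(children))
  list(label = label, support = support, length = length,
       loss = FALSE, children = children)
}

is_leaf <- function(node) length(node$children) == 0L

node_is_loss <- function(node) isTRUE(node$loss)

#' Number of leaves of a tree node
#' @param node a nested tree node
#' @param count_losses include loss stubs in the count
#' @return integer leaf count
#' @keywords internal
n_leaves <- function(node, count_losses = TRUE) {
  if (is_leaf(node)) {
    if (!count_losses && node_is_loss(node)) return(0L)
    return(1L)
  }
  sum(vapply(node$children, n_leaves, integer(1), count_losses = count_losses))
}

#' Leaf labels of a tree, left-to-right
#' @keywords internal
tree_leaves <- function(node, include_losses = FALSE) {
  if (is_leaf(node)) {
    if (!include_losses && node_is_loss(node)) return(character(0))
    return(node$label)
  }
  unlist(lapply(node$children, tree_leaves, include_losses = include_losses))
}

tree_is_binary <- function(node) {
  if (is_leaf(node)) return(TRUE)
  length(node$children) == 2L && all(vapply(node$children, tree_is_binary, logical(1)))
}

#' Count internal nodes (children >= 2)
#' @keywords internal
n_internal <- function(node) {
  if (is_leaf(node)) return(0L)
  1L + sum(vapply(node$children, n_internal, integer(1)))
}

# Flatten a nested gene tree into parallel vectors indexed by preorder id.
# Returns list(parent, children, label, support, loss, order_post, n, root).
flatten_tree <- function(root) {
  parent <- integer(0); label <- character(0); support <- numeric(0)
  loss <- logical(0); children <- list()
  # iterative preorder to avoid deep recursion
  nodes <- list(list(node = root, par = 0L))
  k <- 0L
  while (length(nodes) > 0) {
    cur <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    k <- k + 1L
    parent[k] <- cur$par
    label[k] <- if (is.null(cur$node$label)) NA_character_ else cur$node$label
    support[k] <- if (is.null(cur$node$support)) NA_real_ else cur$node$support
    loss[k] <- node_is_loss(cur$node)
    children[[k]] <- integer(0)
    if (cur$par > 0L) children[[cur$par]] <- c(children[[cur$par]], k)
    ch <- cur$node$children
    if (length(ch) > 0) {
      for (i in rev(seq_along(ch))) {
        nodes[[length(nodes) + 1L]] <- list(node = ch[[i]], par = k)
      }
    }
  }
  n <- k
  post <- postorder_ids(children, 1L)
  list(parent = parent, children = children, label = label,
       support = support, loss = loss, order_post = post, n = n, root = 1L)
}

postorder_ids <- function(children, root) {
  out <- integer(0)
  stack <- list(list(id = root, stage = 0L))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (fr$stage == 0L) {
      stack[[length(stack) + 1L]] <- list(id = fr$id, stage = 1L)
      for (c in rev(children[[fr$id]])) {
        stack[[length(stack) + 1L]] <- list(id = c, stage = 0L)
      }
    } else {
      out <- c(out, fr$id)
    }
  }
  out
}

# ---- indexed species tree ----------------------------------------------

#' Build an indexed species tree from a nested node
#'
#' Internal species-tree container: parent/children/depth vectors plus a
#' postorder.  Internal nodes without labels get deterministic synthetic
#' labels so that tallies and count vectors can always be keyed by name.
#'
#' @param root nested tree node (rooted, binary)
#' @return an object of class `stree`
#' @keywords internal
stree_build <- function(root) {
  fl <- flatten_tree(root)
  nch <- lengths(fl$children)
  if (any(nch == 1L) || any(nch > 2L)) {
    stop("species tree must be strictly binary (every internal node has 2 children)")
  }
  leaves <- which(nch == 0L)
  if (anyDuplicated(fl$label[leaves])) stop("duplicate species leaf labels")
  if (any(is.na(fl$label[leaves]) | fl$label[leaves] == "")) {
    stop("species leaf labels must be non-empty")
  }
  lab <- fl$label
  need <- which(nch > 0L & (is.na(lab) | lab == ""))
  if (length(need) > 0) lab[need] <- paste0("anc", seq_along(need))
  if (anyDuplicated(lab)) stop("species node labels must be unique after auto-labelling")
  depth <- integer(fl$n)
  for (v in seq_len(fl$n)) {
    if (fl$parent[v] > 0L) depth[v] <- depth[fl$parent[v]] + 1L
  }
  structure(list(parent = fl$parent, children = fl$children, label = lab,
                 depth = depth, is_leaf = nch == 0L,
                 postorder = fl$order_post, root = 1L, n = fl$n,
                 node = root),
            class = "stree")
}

#' @export
print.stree <- function(x, ...) {
  cat("Species tree:", sum(x$is_leaf), "leaves,", x$n, "nodes\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

stree_leaf_index <- function(S) {
  idx <- which(S$is_leaf)
  stats::setNames(idx, S$label[idx])
}

# LCA of two node indices by depth walking (trees are desk scale).
stree_lca2 <- function(S, a, b) {
  while (a != b) {
    if (S$depth[a] < S$depth[b]) b <- S$parent[b] else a <- S$parent[a]
  }
  a
}

stree_lca <- function(S, ids) {
  ids <- unique(ids)
  a <- ids[1]
  for (b in ids[-1]) a <- stree_lca2(S, a, b)
  a
}

# TRUE if `anc` is an ancestor of (or equal to) `des`.
stree_is_ancestor <- function(S, anc, des) {
  while (des != 0L) {
    if (des == anc) return(TRUE)
    des <- S$parent[des]
  }
  FALSE
}

# Node indices on the path anc -> des, excluding both endpoints.
stree_path_between <- function(S, anc, des) {
  out <- integer(0)
  v <- S$parent[des]
  while (v != anc && v != 0L) {
    out <- c(out, v)
    v <- S$parent[v]
  }
  if (v != anc) stop("internal error: not an ancestor")
  rev(out)
}

# Preorder ids of the subtree rooted at r.
stree_subtree <- function(S, r) {
  out <- integer(0); stack <- r
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(S$children[[v]]))
  }
  out
}
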