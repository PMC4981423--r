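#' Contract weakly supported branches
#'
#' Every internal branch whose support is strictly below `threshold` is
#' deleted and its endpoints merged, creating polytomies.  Leaf branches
#' and the root are never contracted.  Branches without a support value
#' are treated as fully supported (`missing = "keep"`) unless
#' `missing = "contract"`.
#'
#' @param G gene tree (nested node)
#' @param threshold support threshold in \[0, 1\]; branches with
#'   `support < threshold` are contracted (ties are kept)
#' @param missing `"keep"` or `"contract"`: what to do with branches that
#'   carry no support value
#' @return a (possibly multifurcating) gene tree
#' @examples
#' g <- parse_newick("(((a1,a2)0.5,b1)0.99,c1);", "gene")
#' write_newick(contract_low_support(g, 0.95))
#' @export
contract_low_support <- function(G, threshold, missing = c("keep", "contract")) {
  missing <- match.arg(missing)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  rec <- function(node) {
    if (is_leaf(node)) return(node)
    new_children <- list()
    for (ch in node$children) {
      ch <- rec(ch)
      weak <- if (!is_leaf(ch)) {
        if (is.na(ch$support)) missing == "contract" else ch$support < threshold
      } else FALSE
      if (weak) {
        new_children <- c(new_children, ch$children)
      } else {
        new_children <- c(new_children, list(ch))
      }
    }
    node$children <- new_children
    node
  }
  as_gtree(rec(G))
}

#' Enumerate candidate rootings of an unrooted gene tree
#'
#' One rooted candidate per branch of the tree: the branch is subdivided
#' and the new vertex becomes the root.  Candidates are produced in
#' postorder of the branch's lower endpoint, which is also the
#' deterministic tie-break order used when several rootings achieve the
#' same reconciliation cost.  A binary unrooted tree with n leaves yields
#' 2n - 3 candidates.
#'
#' @param G gene tree whose root multifurcation represents an unrooted tree
#' @return list of rooted gene trees
#' @export
enumerate_rootings <- function(G) {
  fl <- flatten_tree(G)
  if (sum(lengths(fl$children) == 0L) < 3L) stop("need at least 3 leaves to root")
  adj <- vector("list", fl$n)
  for (v in seq_len(fl$n)) {
    p <- fl$parent[v]
    if (p > 0L) {
      adj[[p]] <- c(adj[[p]], v)
      adj[[v]] <- c(adj[[v]], p)
    }
  }
  # support/length of the branch between a and b = those stored on the
  # lower endpoint in the input orientation
  edge_sup <- function(a, b) if (fl$parent[a] == b) fl$support[a] else fl$support[b]
  orient <- function(a, from) {
    nb <- setdiff(adj[[a]], from)
    if (length(nb) == 0L) return(g_leaf(fl$label[a]))
    g_node(lapply(nb, orient, from = a),
           label = NA_character_, support = edge_sup(a, from))
  }
  out <- list()
  for (v in fl$order_post) {
    p <- fl$parent[v]
    if (p == 0L) next
    left <- orient(v, p)
    right <- orient(p, v)
    s <- edge_sup(v, p)
    left$support <- if (is_leaf(left)) left$support else s
    right$support <- if (is_leaf(right)) right$support else s
    out[[length(out) + 1L]] <- as_gtree(g_node(list(left, right)))
  }
  out
}

#' Extract polytomies of a rooted multifurcating tree, bottom-up
#'
#' Returns one descriptor per node with three or more children, in
#' postorder, so that resolving them in the returned order never
#' encounters an unresolved polytomy inside a child subtree.
#'
#' @param G rooted gene tree
#' @return list of descriptors: `node` (the multifurcating subtree),
#'   `path` (integer vector of child positions from the root; empty for
#'   the root itself), `degree` (number of children)
#' @export
extract_polytomies <- function(G) {
  out <- list()
  rec <- function(node, path) {
    for (i in seq_along(node$children)) {
      rec(node$children[[i]], c(path, i))
    }
    if (length(node$children) >= 3L) {
      out[[length(out) + 1L]] <<- list(node = node, path = path,
                                       degree = length(node$children))
    }
  }
  rec(G, integer(0))
  out
}
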