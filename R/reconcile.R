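#' Duplication/loss cost scheme
#'
#' Weights applied to duplication and loss events when scoring a
#' reconciliation.  Both must be finite and nonnegative and not both zero.
#' The production setting used for large database runs is
#' `cost_scheme(1, 0.99999)`, which breaks ties in favour of losses.
#'
#' @param dup duplication cost (default 1)
#' @param loss loss cost (default 1)
#' @return a `cost_scheme` list with elements `dup`, `loss`
#' @export
cost_scheme <- function(dup = 1, loss = 1) {
  if (!is.finite(dup) || !is.finite(loss) || dup < 0 || loss < 0) {
    stop("costs must be finite and nonnegative")
  }
  if (dup == 0 && loss == 0) stop("duplication and loss costs cannot both be zero")
  structure(list(dup = dup, loss = loss), class = "cost_scheme")
}

#' LCA mapping of a rooted binary gene tree onto the species tree
#'
#' Each leaf maps to its species (loss stubs carry their species label
#' directly); each internal node maps to the lowest common ancestor of its
#' children's images.  Leaves may map to internal species nodes, which is
#' what the brute-force polytomy oracle needs for pre-resolved subtrees.
#'
#' @param G rooted binary gene tree (nested node)
#' @param S species tree (`stree`)
#' @param map named character vector gene leaf -> species label (ignored
#'   for loss stubs)
#' @return list with the flattened tree (`fl`) and `map_idx`, the species
#'   index per gene node
#' @export
lca_map <- function(G, S, map) {
  fl <- flatten_tree(G)
  map_idx <- integer(fl$n)
  for (v in fl$order_post) {
    if (length(fl$children[[v]]) == 0L) {
      key <- if (fl$loss[v]) fl$label[v] else unname(map[fl$label[v]])
      if (is.na(key) || is.null(key)) stop("unmapped gene leaf: ", fl$label[v])
      idx <- match(key, S$label)
      if (is.na(idx)) stop("species '", key, "' not in species tree")
      map_idx[v] <- idx
    } else {
      map_idx[v] <- stree_lca(S, map_idx[fl$children[[v]]])
    }
  }
  list(fl = fl, map_idx = map_idx)
}

#' Annotate internal nodes as duplications or speciations
#'
#' An internal node is a duplication iff it maps to the same species node
#' as at least one of its children.
#'
#' @param lm result of [lca_map()]
#' @return character vector per gene node: `"leaf"`, `"loss"`,
#'   `"speciation"` or `"duplication"`
#' @export
annotate_events <- function(lm) {
  fl <- lm$fl
  ev <- character(fl$n)
  for (v in seq_len(fl$n)) {
    ch <- fl$children[[v]]
    if (length(ch) == 0L) {
      ev[v] <- if (fl$loss[v]) "loss" else "leaf"
    } else {
      ev[v] <- if (any(lm$map_idx[ch] == lm$map_idx[v])) "duplication" else "speciation"
    }
  }
  ev
}

# Losses implied by one gene-tree edge (p -> v), attributed to species
# nodes: a loss at species node t means a loss on the species-tree edge
# above t (the lineage died on the branch leading into t's subtree).
edge_losses <- function(S, mp, mv, parent_is_dup, child_is_stub) {
  out <- integer(0)
  if (mp != mv) {
    path <- c(mp, stree_path_between(S, mp, mv), mv)
    # speciation at path[i] sends the lineage into path[i+1]; the sibling
    # subtree loses one copy.  A duplication parent additionally speciates
    # at mp itself.
    start <- if (parent_is_dup) 1L else 2L
    g <- length(path)
    if (g >= start + 1L) {
      for (i in seq.int(start, g - 1L)) {
        sib <- setdiff(S$children[[path[i]]], path[i + 1L])
        out <- c(out, sib)
      }
    }
  }
  if (child_is_stub) out <- c(out, mv)
  out
}

#' Count losses of an LCA reconciliation
#'
#' For every gene-tree edge the species path between the two endpoint
#' images is subdivided; each bypassed sibling subtree records one loss on
#' its stem branch.  Loss stubs record one extra loss at their own species
#' node.  Losses are reported per species node, meaning the branch above
#' that node.
#'
#' @param lm result of [lca_map()]
#' @param S species tree
#' @param events result of [annotate_events()] (computed when missing)
#' @return integer vector of length `S$n`: losses on the branch above each
#'   species node
#' @export
count_losses <- function(lm, S, events = NULL) {
  if (is.null(events)) events <- annotate_events(lm)
  fl <- lm$fl
  loss_at <- integer(S$n)
  for (v in seq_len(fl$n)) {
    p <- fl$parent[v]
    if (p == 0L) next
    ids <- edge_losses(S, lm$map_idx[p], lm$map_idx[v],
                       parent_is_dup = events[p] == "duplication",
                       child_is_stub = fl$loss[v])
    for (t in ids) loss_at[t] <- loss_at[t] + 1L
  }
  loss_at
}

#' Ancestral gene content induced by a reconciliation
#'
#' The content at species node `s` is the number of gene lineages entering
#' `s`: gene-tree nodes mapped to `s` whose parent maps elsewhere (or do
#' not have one), plus lineages whose edge passes through `s` on the way
#' to a lower species.  Loss stubs count while they are present in the
#' tree.
#'
#' @param lm result of [lca_map()]
#' @param S species tree
#' @return integer vector of length `S$n`
#' @export
gene_content <- function(lm, S) {
  fl <- lm$fl
  content <- integer(S$n)
  for (v in seq_len(fl$n)) {
    p <- fl$parent[v]
    mv <- lm$map_idx[v]
    if (p == 0L) {
      content[mv] <- content[mv] + 1L
      next
    }
    mp <- lm$map_idx[p]
    if (mp != mv) {
      content[mv] <- content[mv] + 1L
      for (t in stree_path_between(S, mp, mv)) content[t] <- content[t] + 1L
    }
  }
  content
}

#' Reconcile a rooted binary gene tree with a species tree
#'
#' Computes the LCA mapping, event annotation, per-branch loss counts and
#' the total weighted duplication-loss cost.
#'
#' @param G rooted binary gene tree
#' @param S species tree (`stree`)
#' @param map named character vector gene leaf -> species leaf label
#' @param costs a [cost_scheme()]
#' @return object of class `reconciliation`: list with `fl`, `map_idx`,
#'   `events`, `dup_at` (duplications per species node), `loss_at` (losses
#'   on the branch above each species node), `n_dup`, `n_loss`, `cost`,
#'   `content`
#' @examples
#' S <- parse_newick("((a,b),c);", "species")
#' G <- parse_newick("((a1,b1),(a2,c1));", "gene")
#' r <- reconcile(G, S, bind_species(G, S, rule = "prefix"))
#' r$cost
#' @export
reconcile <- function(G, S, map, costs = cost_scheme()) {
  lm <- lca_map(G, S, map)
  ev <- annotate_events(lm)
  loss_at <- count_losses(lm, S, ev)
  dup_at <- integer(S$n)
  for (v in which(ev == "duplication")) {
    dup_at[lm$map_idx[v]] <- dup_at[lm$map_idx[v]] + 1L
  }
  n_dup <- sum(dup_at)
  n_loss <- sum(loss_at)
  structure(list(fl = lm$fl, map_idx = lm$map_idx, events = ev,
                 dup_at = dup_at, loss_at = loss_at,
                 n_dup = n_dup, n_loss = n_loss,
                 cost = costs$dup * n_dup + costs$loss * n_loss,
                 content = gene_content(lm, S),
                 species_labels = S$label, costs = costs),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Reconciliation:", x$n_dup, "duplications,", x$n_loss,
      "losses, cost", x$cost, "\n")
  invisible(x)
}

#' Per-species-branch duplication and loss totals over many families
#'
#' Sums the per-branch event counts of a collection of reconciliations
#' against a common species tree (the machinery behind genome-wide
#' duplication/loss maps).
#'
#' @param recs list of `reconciliation` objects
#' @param S the shared species tree
#' @return data.frame with columns `species`, `duplications`, `losses`
#' @export
branch_tally <- function(recs, S) {
  dup <- integer(S$n); loss <- integer(S$n)
  for (r in recs) {
    if (!identical(r$species_labels, S$label)) {
      stop("reconciliation computed against a different species tree")
    }
    dup <- dup + r$dup_at
    loss <- loss + r$loss_at
  }
  data.frame(species = S$label, duplications = dup, losses = loss,
             stringsAsFactors = FALSE)
}
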