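# End-to-end correction: contraction -> rooting candidates -> per-polytomy
# DP -> NJ realization -> assembled corrected trees ranked by
# reconciliation cost.

#' Correct a gene tree against a species tree
#'
#' Contracts branches with support below `threshold`, optionally
#' enumerates rootings, resolves every polytomy at minimal weighted
#' duplication-loss cost with NJ tie-breaking on `D`, and returns the
#' corrected rooted binary trees ranked by their recomputed
#' reconciliation cost.  All branches of the input with support at or
#' above the threshold are present in every output tree.
#'
#' @param G gene tree (rooted or unrooted; unrooted trees are represented
#'   by a root multifurcation)
#' @param S species tree (`stree`)
#' @param D distance matrix over the gene leaves (dimnames required)
#' @param map named character vector gene leaf -> species leaf; computed
#'   with [bind_species()] and `map_rule` when omitted
#' @param threshold support contraction threshold in \[0, 1\]
#' @param costs a [cost_scheme()]
#' @param root_mode `"best"` (try all rootings, keep the cost-minimal
#'   ones), `"all"` (keep every rooting's solutions) or `"none"` (take the
#'   input root as given, a root multifurcation becoming a polytomy)
#' @param slimit maximum count vectors explored per polytomy
#' @param plimit maximum resolutions retained per candidate rooting
#' @param firstbest return only the first optimal tree
#' @param keep_losses keep loss stubs in the output trees
#' @param map_rule naming rule for [bind_species()] when `map` is missing
#' @return object of class `profnj_result`: list with `trees` (nested
#'   gene trees), `summary` (data.frame: rank, cost, duplications, losses,
#'   rooting), plus the inputs used
#' @examples
#' S <- parse_newick("((a,b),c);", "species")
#' G <- parse_newick("((a1,b1)0.99,((a2,b2)0.3,c1)0.2);", "gene")
#' D <- simulate_distances(parse_newick("((a1,b1),((a2,b2),c1));", "gene"),
#'                         noise_sd = 0, seed = 1)
#' res <- correct_tree(G, S, D, threshold = 0.95, root_mode = "none")
#' res$summary
#' @export
correct_tree <- function(G, S, D, map = NULL, threshold = 0.95,
                         costs = cost_scheme(),
                         root_mode = c("best", "all", "none"),
                         slimit = 1L, plimit = 1L, firstbest = FALSE,
                         keep_losses = FALSE,
                         map_rule = c("suffix", "prefix")) {
  root_mode <- match.arg(root_mode)
  if (is_leaf(G)) stop("empty or single-leaf gene tree")
  if (is.null(map)) map <- bind_species(G, S, rule = match.arg(map_rule))
  leaves <- tree_leaves(G)
  if (is.null(rownames(D)) || !all(leaves %in% rownames(D))) {
    missing <- setdiff(leaves, rownames(D))
    stop("distance matrix lacks gene leaves: ", paste(missing, collapse = ", "))
  }
  D <- D[leaves, leaves, drop = FALSE]
  Gc <- contract_low_support(G, threshold)
  candidates <- if (length(Gc$children) == 2L || root_mode == "none") {
    list(Gc)
  } else {
    enumerate_rootings(Gc)
  }
  out_trees <- list(); out_cost <- numeric(0)
  out_dup <- integer(0); out_loss <- integer(0); out_rooting <- integer(0)
  for (ri in seq_along(candidates)) {
    sols <- resolve_candidate(candidates[[ri]], S, D, map, costs,
                              slimit = slimit, plimit = plimit)
    for (tr in sols) {
      pruned <- prune_loss_stubs(tr)
      rec <- reconcile(pruned, S, map, costs)
      out_trees[[length(out_trees) + 1L]] <-
        as_gtree(if (keep_losses) tr else pruned)
      out_cost <- c(out_cost, rec$cost)
      out_dup <- c(out_dup, rec$n_dup)
      out_loss <- c(out_loss, rec$n_loss)
      out_rooting <- c(out_rooting, ri)
    }
  }
  ord <- rank_outputs(out_cost)
  if (root_mode == "best" && length(ord) > 0) {
    best <- min(out_cost)
    ord <- ord[out_cost[ord] <= best + 1e-9]
  }
  if (firstbest && length(ord) > 0) ord <- ord[1]
  structure(list(
    trees = out_trees[ord],
    summary = data.frame(rank = seq_along(ord), cost = out_cost[ord],
                         duplications = out_dup[ord], losses = out_loss[ord],
                         rooting = out_rooting[ord]),
    map = map, threshold = threshold, costs = costs
  ), class = "profnj_result")
}

#' @export
print.profnj_result <- function(x, ...) {
  cat("Corrected gene trees:", length(x$trees), "solution(s)\n")
  print(x$summary)
  invisible(x)
}

#' Stable ranking of solutions by cost
#'
#' Returns the ordering of `costs` by increasing value; equal costs keep
#' their generation order (stable sort).
#'
#' @param costs numeric vector of reconciliation costs
#' @return integer permutation
#' @export
rank_outputs <- function(costs) {
  order(costs, seq_along(costs), method = "radix")
}

# Resolve all polytomies of one rooted candidate.  Maintains a single
# evolving metric state shared across polytomies (bottom-up), duplicated
# only when several count vectors are explored.  Returns a list of
# completed nested trees (with loss stubs), capped at `plimit`.
resolve_candidate <- function(Groot, S, D, map, costs, slimit, plimit) {
  leaves <- tree_leaves(Groot)
  sp_idx <- match(map[leaves], S$label)
  st0 <- ms_new(D[leaves, leaves, drop = FALSE], species = sp_idx,
                nodes = lapply(leaves, g_leaf), n_members = length(leaves))
  leaf_id <- stats::setNames(seq_along(leaves), leaves)
  nreal <- function(node) n_leaves(node, count_losses = FALSE)

  # returns list of alternatives: list(id=active row, st=state, sp=species idx)
  process <- function(node, st, cap) {
    if (is_leaf(node)) {
      id <- leaf_id[[node$label]]
      return(list(list(id = id, st = st, sp = st$species[id])))
    }
    # resolve children sequentially, carrying the state
    combos <- list(list(ids = integer(0), st = st, sps = integer(0)))
    for (ch in node$children) {
      nxt <- list()
      for (cb in combos) {
        for (alt in process(ch, cb$st, cap)) {
          nxt[[length(nxt) + 1L]] <- list(ids = c(cb$ids, alt$id),
                                          st = alt$st,
                                          sps = c(cb$sps, alt$sp))
          if (length(nxt) >= cap) break
        }
        if (length(nxt) >= cap) break
      }
      combos <- nxt
    }
    out <- list()
    for (cb in combos) {
      if (length(node$children) == 2L) {
        st2 <- cb$st
        sp <- stree_lca2(S, cb$sps[1], cb$sps[2])
        joined <- g_node(list(st2$nodes[[cb$ids[1]]], st2$nodes[[cb$ids[2]]]),
                         label = node$label, support = node$support)
        st2 <- ms_add(st2, sp, joined)
        r <- st2$n
        others <- setdiff(which(st2$alive), c(cb$ids, r))
        w <- vapply(cb$ids, function(i) nreal(st2$nodes[[i]]), numeric(1))
        w <- if (sum(w) > 0) w / sum(w) else c(0.5, 0.5)
        st2$D[r, others] <- w[1] * st2$D[cb$ids[1], others] +
                            w[2] * st2$D[cb$ids[2], others]
        st2$D[others, r] <- st2$D[r, others]
        st2$D[r, r] <- 0
        st2$alive[cb$ids] <- FALSE
        out[[length(out) + 1L]] <- list(id = r, st = st2, sp = sp)
      } else {
        # polytomy: DP + NJ realization, one alternative per count vector
        mult <- tabulate(cb$sps, nbins = S$n)
        tab <- build_table(S, mult, costs)
        vecs <- backtrack_count_vectors(tab, limit = slimit)
        for (V in vecs) {
          st2 <- cb$st
          st2$member[] <- FALSE
          st2$member[cb$ids] <- TRUE
          res <- realize_vector(st2, S, V, costs, root = tab$root)
          st2 <- res$st
          nd <- st2$nodes[[res$root_id]]
          nd$label <- node$label
          nd$support <- node$support
          st2$nodes[[res$root_id]] <- nd
          out[[length(out) + 1L]] <- list(id = res$root_id, st = st2,
                                          sp = tab$root)
          if (length(out) >= cap) break
        }
      }
      if (length(out) >= cap) break
    }
    out
  }
  alts <- process(Groot, st0, max(1L, as.integer(plimit)))
  lapply(alts, function(a) a$st$nodes[[a$id]])
}
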