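# NJ-guided realization of a count vector.
#
# The metric space E starts from the polytomy's children and is
# progressively augmented with the nodes created by joins.  Rows are
# never reused: the insertion index of a node is its row index, which is
# also the deterministic tie-break order.  External rows (other active
# subtrees of the gene tree) ride along: joins update their distances via
# the reduction formula so that later polytomies see reduced rows.

#' Neighbor-Joining pair score
#'
#' `Q(x, y) = (n - 2) D(x, y) - sum_t D(x, t) - sum_t D(y, t)` with `t`
#' ranging over the candidate pool of size `n`.  The pair minimizing Q is
#' joined next.
#'
#' @param D symmetric distance matrix
#' @param pool integer indices of the candidate set (must include x and y)
#' @param x,y indices of the two candidates
#' @return the Q score
#' @export
q_score <- function(D, pool, x, y) {
  n <- length(pool)
  (n - 2) * D[x, y] - sum(D[x, pool]) - sum(D[y, pool])
}

# mutable-ish metric state; all helpers return the updated state
ms_new <- function(D, species, nodes, n_members, capacity = NULL) {
  n <- nrow(D)
  if (is.null(capacity)) capacity <- 4L * n + 16L
  M <- matrix(0, capacity, capacity)
  M[seq_len(n), seq_len(n)] <- D
  list(D = M, species = c(species, integer(capacity - n)),
       isloss = logical(capacity),
       member = c(rep(TRUE, n_members), rep(FALSE, capacity - n_members)),
       alive = c(rep(TRUE, n), rep(FALSE, capacity - n)),
       nodes = c(nodes, vector("list", capacity - length(nodes))),
       n = n)
}

ms_grow <- function(st, extra) {
  cap <- nrow(st$D)
  if (st$n + extra <= cap) return(st)
  newcap <- max(2L * cap, st$n + extra)
  M <- matrix(0, newcap, newcap)
  M[seq_len(cap), seq_len(cap)] <- st$D
  st$D <- M
  st$species <- c(st$species, integer(newcap - cap))
  st$isloss <- c(st$isloss, logical(newcap - cap))
  st$member <- c(st$member, logical(newcap - cap))
  st$alive <- c(st$alive, logical(newcap - cap))
  st$nodes <- c(st$nodes, vector("list", newcap - cap))
  st
}

ms_add <- function(st, species, node, isloss = FALSE, member = TRUE) {
  st <- ms_grow(st, 1L)
  st$n <- st$n + 1L
  i <- st$n
  st$species[i] <- species
  st$isloss[i] <- isloss
  st$member[i] <- member
  st$alive[i] <- TRUE
  st$nodes[[i]] <- node
  if (isloss) {
    live <- which(st$alive)
    st$D[i, live] <- Inf
    st$D[live, i] <- Inf
  }
  st$D[i, i] <- 0
  st
}

# Join x and y into a new node of species `sp`; distances to every other
# live row (members and externals) via the NJ reduction, or copied from
# the real partner when one of the pair is a loss stub.
ms_join <- function(st, x, y, sp) {
  if (st$isloss[x] && st$isloss[y]) {
    stop("internal error: asked to join two loss nodes")
  }
  node <- g_node(list(st$nodes[[x]], st$nodes[[y]]))
  st <- ms_add(st, sp, node)
  r <- st$n
  others <- which(st$alive)
  others <- others[others != x & others != y & others != r]
  if (st$isloss[x]) {
    st$D[r, others] <- st$D[y, others]
  } else if (st$isloss[y]) {
    st$D[r, others] <- st$D[x, others]
  } else {
    st$D[r, others] <- (st$D[x, others] + st$D[y, others] - st$D[x, y]) / 2
  }
  st$D[others, r] <- st$D[r, others]
  st$D[r, r] <- 0
  st$alive[x] <- FALSE
  st$alive[y] <- FALSE
  st
}

# Deterministic argmin-Q pair among candidate pairs (xs x ys), with the
# Q sums running over the pool of real candidates; lexicographic
# (insertion index of x, then y) tie-break.
choose_pair <- function(st, xs, ys) {
  rx <- xs[!st$isloss[xs]]
  ry <- ys[!st$isloss[ys]]
  if (length(rx) == 0L && length(ry) == 0L) {
    stop("internal error: asked to join two loss nodes")
  }
  if (length(rx) == 0L) return(c(min(xs[st$isloss[xs]]), min(ry)))
  if (length(ry) == 0L) return(c(min(rx), min(ys[st$isloss[ys]])))
  pool <- sort(unique(c(rx, ry)))
  best <- Inf; bx <- NA_integer_; by <- NA_integer_
  for (x in sort(rx)) {
    for (y in sort(ry)) {
      if (x == y) next
      q <- q_score(st$D, pool, x, y)
      if (q < best - 1e-12) {
        best <- q; bx <- x; by <- y
      }
    }
  }
  c(bx, by)
}

# Core engine shared by the exported resolver and the pipeline: realizes
# count vector V on state `st` whose member rows are the polytomy's
# children.  Returns list(st, root_row, joins, losses).
realize_vector <- function(st, S, V, costs, root = NULL) {
  if (is.null(root)) {
    # topmost species node carrying a lineage; its ancestors carry none
    pos <- which(V > 0)
    if (length(pos) == 0L) stop("empty count vector")
    root <- pos[which.min(S$depth[pos])]
  }
  if (V[root] != 1L) stop("count vector must assign one lineage to the table root")
  joins <- 0L; losses <- 0L
  sub <- stree_subtree(S, root)
  post <- intersect(S$postorder, sub)
  Es <- function(s) which(st$alive & st$member & st$species == s)
  for (s in post) {
    if (!S$is_leaf[s]) {
      ch <- S$children[[s]]
      nsp <- V[ch[1]]
      if (V[ch[2]] != nsp) stop("count vector violates sibling equality")
      if (nsp > 0L) {
        for (i in seq_len(nsp)) {
          el <- Es(ch[1]); er <- Es(ch[2])
          if (length(el) == 0L || length(er) == 0L) {
            stop("count vector infeasible: empty candidate set at species '",
                 S$label[s], "'")
          }
          pr <- choose_pair(st, el, er)
          st <- ms_join(st, pr[1], pr[2], s)
          joins <- joins + 1L
        }
      }
    }
    m_s <- length(Es(s))
    if (m_s > V[s]) {
      for (i in seq_len(m_s - V[s])) {
        es <- Es(s)
        pr <- choose_pair(st, es, es)
        st <- ms_join(st, pr[1], pr[2], s)
        joins <- joins + 1L
      }
    } else if (m_s < V[s]) {
      for (i in seq_len(V[s] - m_s)) {
        st <- ms_add(st, s, g_leaf(S$label[s], loss = TRUE), isloss = TRUE)
        losses <- losses + 1L
      }
    }
  }
  fin <- which(st$alive & st$member)
  if (length(fin) != 1L) {
    stop("internal error: resolution left ", length(fin), " live nodes")
  }
  list(st = st, root_id = fin, joins = joins, losses = losses)
}

#' Resolve a polytomy into a binary subtree realizing a count vector
#'
#' Implements the bottom-up join schedule over the species tree: for each
#' internal species node, `V` speciation joins pair genes from the two
#' child species; surplus genes are then joined as duplications and
#' missing genes inserted as loss stubs with infinite distances.  Joins
#' are chosen by the NJ criterion on `D`.
#'
#' @param S species tree
#' @param children list of child subtrees (nested nodes; a plain label
#'   string is promoted to a leaf)
#' @param child_species character or integer species of each child's root
#' @param V count vector from [backtrack_count_vectors()]
#' @param D distance matrix over the children, in the same order (extra
#'   trailing rows/columns are treated as external nodes: never joined but
#'   kept up to date through the reductions)
#' @param costs a [cost_scheme()] (recorded, not used in the joins)
#' @param keep_losses keep loss stubs in the returned tree (default TRUE;
#'   see [prune_loss_stubs()])
#' @return list with `tree` (rooted binary nested node), `joins`,
#'   `losses`, and `extern_row` (distances of the new root to the external
#'   rows of `D`, if any)
#' @export
resolve_polytomy <- function(S, children, child_species, V, D,
                             costs = cost_scheme(), keep_losses = TRUE) {
  n <- length(children)
  stopifnot(n >= 1, nrow(D) >= n, nrow(D) == ncol(D))
  children <- lapply(children, function(c) if (is.character(c)) g_leaf(c) else c)
  sp <- if (is.character(child_species)) match(child_species, S$label) else child_species
  if (anyNA(sp)) stop("unknown child species")
  n_ext <- nrow(D) - n
  st <- ms_new(D, species = c(sp, integer(n_ext)),
               nodes = c(children, vector("list", n_ext)), n_members = n)
  res <- realize_vector(st, S, V, costs)
  tree <- res$st$nodes[[res$root_id]]
  if (!keep_losses) tree <- prune_loss_stubs(tree)
  ext_row <- if (n_ext > 0) res$st$D[res$root_id, n + seq_len(n_ext)] else numeric(0)
  list(tree = as_gtree(tree), joins = res$joins, losses = res$losses,
       extern_row = ext_row)
}

#' Remove loss stubs from a resolved tree
#'
#' Deletes artificial loss leaves and suppresses the resulting unary
#' nodes.  Returns `NULL` if everything was a stub.
#'
#' @param node nested tree node
#' @return pruned tree node or `NULL`
#' @export
prune_loss_stubs <- function(node) {
  if (is_leaf(node)) {
    if (node_is_loss(node)) return(NULL)
    return(node)
  }
  kept <- Filter(Negate(is.null), lapply(node$children, prune_loss_stubs))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1]])
  node$children <- kept
  node
}
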