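#' Parse a Newick string into a gene or species tree
#'
#' Trees are parsed with \pkg{ape} and converted to the package's internal
#' representation.  For gene trees, internal-node labels that parse as a
#' number are interpreted as branch supports: values in \[0, 1\] are taken
#' as-is (aLRT convention), values in (1, 100\] are divided by 100
#' (bootstrap percentage convention).  Species trees must be rooted and
#' strictly binary and may not carry duplicate leaf labels.
#'
#' @param text a Newick string (single tree, terminated by `;`)
#' @param kind `"gene"` or `"species"`
#' @return for `kind = "gene"`, a nested gene-tree node (class `gtree`);
#'   for `kind = "species"`, an indexed species tree (class `stree`)
#' @examples
#' g <- parse_newick("((a1,b1)0.99:0.1,c1:0.2);", "gene")
#' s <- parse_newick("((a,b),c);", "species")
#' @export
parse_newick <- function(text, kind = c("gene", "species")) {
  kind <- match.arg(kind)
  ph <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(ph)) stop("Newick parse error: no tree found in input")
  if (inherits(ph, "multiPhylo")) ph <- ph[[1]]
  root <- phylo_to_node(ph, supports = (kind == "gene"))
  if (kind == "species") return(stree_build(root))
  lv <- tree_leaves(root)
  if (anyDuplicated(lv)) stop("duplicate gene leaf labels: ",
                              paste(unique(lv[duplicated(lv)]), collapse = ", "))
  as_gtree(root)
}

as_gtree <- function(node) {
  class(node) <- c("gtree", "list")
  node
}

#' @export
print.gtree <- function(x, ...) {
  cat("Gene tree:", n_leaves(x), "leaves",
      if (tree_is_binary(x)) "(binary)" else "(multifurcating)", "\n")
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# Convert an ape phylo object into a nested node.
phylo_to_node <- function(ph, supports = TRUE) {
  ntip <- length(ph$tip.label)
  nlab <- ph$node.label
  elen <- ph$edge.length
  kids <- split(seq_len(nrow(ph$edge)), ph$edge[, 1])
  build <- function(v, edge_row) {
    len <- if (!is.null(elen) && !is.na(edge_row)) elen[edge_row] else NA_real_
    if (v <= ntip) return(g_leaf(ph$tip.label[v], length = len))
    lab <- if (!is.null(nlab)) nlab[v - ntip] else NA_character_
    sup <- NA_real_
    if (supports && !is.null(lab) && !is.na(lab) && nzchar(lab)) {
      num <- suppressWarnings(as.numeric(lab))
      if (!is.na(num) && num >= 0 && num <= 100) {
        sup <- if (num > 1) num / 100 else num
        lab <- NA_character_
      }
    }
    if (!is.null(lab) && !is.na(lab) && !nzchar(lab)) lab <- NA_character_
    rows <- kids[[as.character(v)]]
    ch <- lapply(rows, function(r) build(ph$edge[r, 2], r))
    g_node(ch, label = lab, support = sup, length = len)
  }
  build(ntip + 1L, NA_integer_)
}

# Convert a nested node to an ape phylo object (loss stubs kept as leaves).
node_to_phylo <- function(root) {
  ape::read.tree(text = write_newick(root))
}

#' Serialize a tree to Newick
#'
#' Internal-node supports are written as internal labels; branch lengths
#' are written when present.  The output re-parses to an identical tree
#' (topology, labels, supports, lengths to 1e-9).
#'
#' @param tree a gene tree node or an `stree`
#' @param file optional path; when given the string is written there
#' @return the Newick string, invisibly when `file` is given
#' @export
write_newick <- function(tree, file = NULL) {
  if (inherits(tree, "stree")) tree <- tree$node
  fmt <- function(x) sprintf("%.12g", x)
  rec <- function(node, top) {
    if (is_leaf(node)) {
      s <- node$label
    } else {
      inner <- paste(vapply(node$children, rec, character(1), top = FALSE),
                     collapse = ",")
      lab <- if (!is.na(node$support)) fmt(node$support)
             else if (!is.na(node$label)) node$label else ""
      s <- paste0("(", inner, ")", lab)
    }
    if (!top && !is.na(node$length)) s <- paste0(s, ":", fmt(node$length))
    s
  }
  out <- paste0(rec(tree, TRUE), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Read a square PHYLIP-style distance matrix
#'
#' Relaxed dialect: first non-blank line holds the taxon count `n`,
#' followed by `n` rows of a whitespace-delimited label and `n` numbers
#' (labels of any length).  Small asymmetries (at most `tol`) are averaged
#' away; larger ones are an error.  `Inf` entries are accepted.
#'
#' @param text a character string or vector of lines; or use `file`
#' @param file path to a matrix file
#' @param tol maximum tolerated absolute asymmetry (default 1e-6)
#' @return a symmetric numeric matrix with taxon dimnames
#' @export
read_distance_matrix <- function(text = NULL, file = NULL, tol = 1e-6) {
  if (is.null(text)) text <- readLines(file)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  n <- suppressWarnings(as.integer(trimws(text[1])))
  if (is.na(n) || n < 1) stop("first line must be the taxon count")
  if (length(text) != n + 1L) stop("expected ", n, " matrix rows, found ", length(text) - 1L)
  labs <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(text[i + 1L]), "\\s+")[[1]]
    if (length(tok) != n + 1L) {
      stop("row ", i, ": expected a label and ", n, " values, found ",
           length(tok) - 1L)
    }
    labs[i] <- tok[1]
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals)) stop("row ", i, ": non-numeric distance entry")
    D[i, ] <- vals
  }
  if (anyDuplicated(labs)) stop("duplicate taxon labels in distance matrix")
  if (any(D < 0, na.rm = TRUE)) stop("negative distance entries are not allowed")
  asym <- abs(D - t(D))
  fin <- is.finite(asym)
  if (any(asym[fin] > tol)) {
    ij <- which(asym == max(asym[fin]), arr.ind = TRUE)[1, ]
    stop("asymmetric distances beyond tolerance at (", labs[ij[1]], ", ",
         labs[ij[2]], "): ", D[ij[1], ij[2]], " vs ", D[ij[2], ij[1]])
  }
  D <- (D + t(D)) / 2
  D[is.nan(D)] <- Inf  # Inf + Inf averaging
  diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  D
}

#' Write a distance matrix in square PHYLIP format
#' @param D symmetric numeric matrix with dimnames
#' @param file path to write to
#' @return the path, invisibly
#' @export
write_distance_matrix <- function(D, file) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  lines <- c(as.character(nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(rownames(D)[i], sprintf("%.12g", D[i, ])),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, file)
  invisible(file)
}

#' Bind gene-tree leaves to species-tree leaves
#'
#' Builds the total gene-to-species map used by reconciliation.  An
#' explicit two-column table (gene, species) always wins; remaining leaves
#' are resolved by the naming rule: `"suffix"` takes the part after the
#' last underscore (`geneA_homsap -> homsap`), `"prefix"` strips trailing
#' digits (`b2 -> b`).
#'
#' @param G gene tree
#' @param S species tree (`stree`)
#' @param rule `"suffix"` or `"prefix"`
#' @param table optional data.frame/matrix with columns gene, species, or a
#'   named character vector (names = genes)
#' @return named character vector: gene leaf -> species leaf label
#' @export
bind_species <- function(G, S, rule = c("suffix", "prefix"), table = NULL) {
  rule <- match.arg(rule)
  leaves <- tree_leaves(G)
  sp_leaves <- S$label[S$is_leaf]
  tab <- character(0)
  if (!is.null(table)) {
    if (is.data.frame(table) || is.matrix(table)) {
      tab <- stats::setNames(as.character(table[, 2]), as.character(table[, 1]))
    } else {
      tab <- table
    }
  }
  img <- vapply(leaves, function(g) {
    if (g %in% names(tab)) return(unname(tab[g]))
    s <- switch(rule,
      suffix = if (grepl("_", g, fixed = TRUE)) sub(".*_", "", g) else g,
      prefix = sub("[0-9]+$", "", g))
    if (!nzchar(s)) stop("cannot resolve species for gene leaf '", g, "'")
    s
  }, character(1))
  bad <- setdiff(unique(img), sp_leaves)
  if (length(bad) > 0) {
    stop("mapped species not present in species tree: ",
         paste(bad, collapse = ", "))
  }
  img
}

#' Read a two-column gene-to-species table (TSV)
#' @param file path; two whitespace-separated columns, gene then species
#' @return named character vector usable as `table` in [bind_species()]
#' @export
read_species_map <- function(file) {
  tab <- utils::read.table(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("mapping table needs two columns: gene, species")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}
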