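#' @import rlang
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_cols bind_rows filter group_by left_join
#'   mutate n rename select summarise ungroup distinct pull slice
#' @importFrom purrr map map_chr map_dbl map_int map_lgl
#' @keywords internal
"_PACKAGE"

# Node ids follow the ape convention: tips are 1..Ntip in tip.label order,
# the root is Ntip + 1, further internal nodes Ntip + 2 .. Ntip + Nnode.

n_all_nodes <- function(tree) ape::Ntip(tree) + tree$Nnode

root_node <- function(tree) ape::Ntip(tree) + 1L

#' @keywords internal
is_leaf <- function(tree, node) node <= ape::Ntip(tree)

# parent of each node (0 for the root), indexed by node id
parent_vec <- function(tree) {
  p <- integer(n_all_nodes(tree))
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# list of integer child vectors, indexed by node id, in the tree's edge order
children_list <- function(tree) {
  ch <- vector("list", n_all_nodes(tree))
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    ch[[a]] <- c(ch[[a]], tree$edge[i, 2])
  }
  ch
}

# preorder (parent before children); reversing it yields an order where every
# child precedes its parent, which is all the bottom-up passes need
preorder_nodes <- function(tree) {
  ch <- children_list(tree)
  out <- integer(n_all_nodes(tree))
  stack <- root_node(tree)
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- v
    kids <- ch[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

# branch length of the edge above each node (NA for the root);
# trees without branch lengths get NA everywhere
edge_length_vec <- function(tree) {
  len <- rep(NA_real_, n_all_nodes(tree))
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  len
}

# cumulative root-to-node path length; edges without a stored length
# contribute 0 (callers flag this)
node_depths <- function(tree) {
  len <- edge_length_vec(tree)
  len[is.na(len)] <- 0
  par <- parent_vec(tree)
  d <- numeric(n_all_nodes(tree))
  for (v in preorder_nodes(tree)) {
    if (par[v] > 0L) d[v] <- d[par[v]] + len[v]
  }
  d
}

# display label for any node id: tip label, internal label when present,
# otherwise "" (used in CSV exports)
node_labels <- function(tree) {
  lab <- character(n_all_nodes(tree))
  lab[seq_len(ape::Ntip(tree))] <- tree$tip.label
  if (!is.null(tree$node.label)) {
    lab[ape::Ntip(tree) + seq_len(tree$Nnode)] <- tree$node.label
  }
  lab
}

assert_phylo <- function(tree, arg = "tree") {
  if (!inherits(tree, "phylo")) {
    abort(sprintf("`%s` must be a `phylo` tree (see `parse_newick()`).", arg))
  }
  invisible(tree)
}

# deterministic numeric formatting for SVG / Newick output
fmt_num <- function(x, digits = 6) {
  s <- formatC(x, format = "fg", digits = digits)
  trimws(s)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}
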