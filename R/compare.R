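# Multi-method comparison of reconstructions on one tree.

#' Majority state of a probability distribution
#'
#' Argmax over a named probability vector, with lexicographic tie-breaking;
#' a tie is flagged via `attr(, "tie")`. This is the reduction applied to
#' distribution-valued annotations before any transition analysis: only the
#' annotation with the greatest probability is considered.
#'
#' @param p Named numeric vector (names = states).
#' @return The winning state (character scalar) with attribute `tie`.
#' @export
majority_state <- function(p) {
  if (is.null(names(p)) || !length(p)) abort("`p` must be a non-empty named vector.")
  p <- p[order(names(p))]
  top <- p >= max(p) - 1e-12
  out <- names(p)[which(top)[1]]
  attr(out, "tie") <- sum(top) >= 2L
  out
}

#' Compare reconstructions node by node
#'
#' Reduces every supplied reconstruction to one state per node (see
#' [as_node_states()]) and flags the nodes where at least two methods
#' disagree. By default only internal nodes are compared, since tip states
#' are shared inputs; set `include_tips = TRUE` to compare all nodes.
#'
#' @param reconstructions Named list of two or more reconstruction objects
#'   covering every node of `tree`.
#' @param tree The common `phylo` tree.
#' @param include_tips Compare tips as well as internal nodes.
#' @return An object of class `comparison`: `table` (tibble `node`, one
#'   state column per method, `agree`), `discrepant` (integer node ids),
#'   `methods`, `n_discrepant`.
#' @export
discrepant_nodes <- function(reconstructions, tree, include_tips = FALSE) {
  assert_phylo(tree)
  if (length(reconstructions) < 2L) abort("Need at least two reconstructions.")
  if (is.null(names(reconstructions)) || any(!nzchar(names(reconstructions)))) {
    names(reconstructions) <- paste0("method", seq_along(reconstructions))
  }
  nn <- n_all_nodes(tree)
  nodes <- if (include_tips) seq_len(nn) else (ape::Ntip(tree) + 1L):nn
  mat <- vapply(reconstructions, function(r) {
    st <- full_state_vec(tree, r)
    st[nodes]
  }, character(length(nodes)))
  agree <- apply(mat, 1, function(row) length(unique(row)) == 1L)
  tab <- bind_cols(tibble(node = nodes), as_tibble(mat), tibble(agree = agree))
  structure(
    list(
      table = tab,
      discrepant = nodes[!agree],
      methods = names(reconstructions),
      n_discrepant = sum(!agree)
    ),
    class = "comparison"
  )
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf(
    "<comparison> %s: %d discrepant node(s) of %d compared\n",
    paste(x$methods, collapse = " vs "), x$n_discrepant, nrow(x$table)
  ))
  invisible(x)
}

# root-to-node state sequence key for every node of a map
map_path_keys <- function(map) {
  nd <- map$nodes
  key <- character(nrow(nd))
  for (i in order(nd$id)) { # parents precede children by construction
    p <- nd$parent[i]
    key[i] <- if (p == 0L) nd$state[i] else paste(key[nd$id == p], nd$state[i], sep = "\r")
  }
  key
}

#' Mark shared and unique nodes between two transition maps
#'
#' A map node is *shared* when the other map contains a node with the
#' identical root-to-node state sequence (path-consistent structure); with
#' `key = "local"` only the local transition (parent state, state) is
#' compared. The relation is symmetric and reflexive.
#'
#' @param map_a,map_b Two `transition_map`s of the same type over the same
#'   alphabet.
#' @param key `"path"` (default) or `"local"`.
#' @return A list with tibbles `a` and `b` (`id`, `state`, `count`,
#'   `shared`) marking each map's nodes.
#' @export
map_compatibility <- function(map_a, map_b, key = c("path", "local")) {
  key <- match.arg(key)
  if (!inherits(map_a, "transition_map") || !inherits(map_b, "transition_map")) {
    abort("Both arguments must be transition_maps.")
  }
  if (map_a$type != map_b$type) abort("Maps must be of the same type.")
  keys_of <- function(m) {
    if (key == "path") map_path_keys(m)
    else paste(ifelse(is.na(m$nodes$from), "", m$nodes$from), m$nodes$state, sep = "\r")
  }
  ka <- keys_of(map_a)
  kb <- keys_of(map_b)
  mark <- function(m, own, other) {
    tibble(id = m$nodes$id, state = m$nodes$state, count = m$nodes$count,
           shared = own %in% other)
  }
  list(a = mark(map_a, ka, kb), b = mark(map_b, kb, ka))
}
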