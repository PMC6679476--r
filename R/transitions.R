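# Transition extraction and scenario summaries.
#
# A transition is a change of reconstructed state between a node and its
# parent, read top-down from the root. The summaries built here are the
# three transition-map collapse levels, count / relative-rate matrices,
# wildcard path queries, the ambiguity filter and the descendant-size (Sz)
# score.

#' Coerce a reconstruction to a per-node state table
#'
#' Accepts a plain `node`/`state` tibble, a `parsimony_fit`, a `joint_fit`,
#' or a `marginal_posteriors` object (reduced to the majority state per
#' node, lexicographic ties).
#'
#' @param x A reconstruction object.
#' @return A tibble with columns `node`, `state`.
#' @export
as_node_states <- function(x) {
  if (inherits(x, "parsimony_fit") || inherits(x, "joint_fit")) return(x$states)
  if (inherits(x, "marginal_posteriors")) return(select(map_states(x), "node", "state"))
  if (is.data.frame(x)) {
    if (!all(c("node", "state") %in% names(x))) {
      abort("State table must have columns `node` and `state`.")
    }
    return(arrange(as_tibble(x)[c("node", "state")], .data$node))
  }
  abort("Cannot interpret `x` as per-node states.")
}

full_state_vec <- function(tree, states) {
  st <- as_node_states(states)
  nn <- n_all_nodes(tree)
  v <- rep(NA_character_, nn)
  v[st$node] <- st$state
  miss <- which(is.na(v))
  if (length(miss)) {
    abort(sprintf(
      "Unannotated node(s): %s", paste(utils::head(miss, 10), collapse = ", ")
    ))
  }
  v
}

#' Extract transition events from an annotated tree
#'
#' One event per edge whose endpoint states differ, in preorder. The event
#' is attributed to the child endpoint; its distance is the sum of branch
#' lengths from the root to that node (edges without stored lengths count 0
#' and set `attr(, "lengths_missing")`).
#'
#' @param tree A rooted `phylo` tree.
#' @param states Per-node states (anything accepted by [as_node_states()]),
#'   covering every node.
#' @return A tibble of class `transition_events` with columns `node`, `from`,
#'   `to`, `distance`.
#' @export
extract_transitions <- function(tree, states) {
  assert_phylo(tree)
  st <- full_state_vec(tree, states)
  par <- parent_vec(tree)
  dep <- node_depths(tree)
  pre <- preorder_nodes(tree)
  ev <- pre[par[pre] != 0L]
  ev <- ev[st[ev] != st[par[ev]]]
  out <- tibble(
    node = ev,
    from = st[par[ev]],
    to = st[ev],
    distance = dep[ev]
  )
  attr(out, "alphabet") <- sort(unique(st))
  attr(out, "lengths_missing") <- is.null(tree$edge.length)
  class(out) <- c("transition_events", class(out))
  out
}

new_transition_map <- function(nodes, type, alphabet) {
  structure(list(nodes = nodes, type = type, alphabet = alphabet),
            class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
  cat(sprintf(
    "<transition_map> type %d: %d node(s), %d transition(s)\n",
    x$type, nrow(x$nodes), sum(x$nodes$count[x$nodes$parent != 0L])
  ))
  invisible(x)
}

#' Build the type-1 transition map
#'
#' The map starts at a root carrying the tree root's state; reading the
#' annotated tree top-down, every transition `i -> j` creates a map node
#' (state `j`) whose map parent is the nearest ancestral transition (or the
#' map root). Equivalently: the annotated tree contracted along
#' state-constant edges. Each map node stores the tree nodes it represents,
#' a collapse count (always 1 off the root in type 1) and the event's
#' root-to-node distance.
#'
#' @inheritParams extract_transitions
#' @return A `transition_map` (fields `nodes`, `type`, `alphabet`); `nodes`
#'   is a tibble `id`, `parent` (0 for the map root), `from` (parent state,
#'   NA at the root), `state`, `count`, `dist`, `members` (list of tree node
#'   ids).
#' @export
build_map_type1 <- function(tree, states) {
  assert_phylo(tree)
  st <- full_state_vec(tree, states)
  par <- parent_vec(tree)
  dep <- node_depths(tree)
  r <- root_node(tree)
  nn <- n_all_nodes(tree)
  map_of <- integer(nn) # map node owning each tree node
  id <- integer(0); parent <- integer(0); from <- character(0)
  state <- character(0); dist <- numeric(0); members <- list()
  add_node <- function(p, fr, s, d, member) {
    k <- length(id) + 1L
    id[k] <<- k; parent[k] <<- p; from[k] <<- fr
    state[k] <<- s; dist[k] <<- d; members[[k]] <<- member
    k
  }
  add_node(0L, NA_character_, st[r], 0, r)
  map_of[r] <- 1L
  for (v in preorder_nodes(tree)) {
    p <- par[v]
    if (p == 0L) next
    if (st[v] != st[p]) {
      map_of[v] <- add_node(map_of[p], st[p], st[v], dep[v], v)
    } else {
      map_of[v] <- map_of[p]
      members[[map_of[p]]] <- c(members[[map_of[p]]], v)
    }
  }
  nodes <- tibble(
    id = id, parent = parent, from = from, state = state,
    count = rep(1L, length(id)), dist = dist, members = members
  )
  new_transition_map(nodes, 1L, sort(unique(st)))
}

#' Collapse a transition map to type 2 or type 3
#'
#' `collapse_type2()` merges sibling map nodes representing the same
#' transition (same parent node in the type-1 map, same child state):
#' counts sum, member sets union, distances take the minimum; the merge
#' recurses top-down so that the children of merged nodes are merged
#' against each other. `collapse_type3()` goes one step further on a type-2
#' map: all nodes representing the same transition `i -> j` (their parents
#' necessarily share state `i`) are folded into one node, attached under
#' the first parent encountered top-down, their children re-routed and
#' re-merged by the same rule.
#'
#' @param map A `transition_map` of type 1 (for `collapse_type2`) or
#'   type 2 (for `collapse_type3`).
#' @return A `transition_map` of the next type. Total non-root counts are
#'   conserved.
#' @export
collapse_type2 <- function(map) {
  if (!inherits(map, "transition_map") || map$type != 1L) {
    abort("`collapse_type2()` expects a type-1 transition map.")
  }
  old <- map$nodes
  old_children <- split(old$id, factor(old$parent, levels = c(0L, old$id)))
  id <- integer(0); parent <- integer(0); from <- character(0)
  state <- character(0); count <- integer(0); dist <- numeric(0); members <- list()
  add <- function(p, fr, s, cnt, d, mem) {
    k <- length(id) + 1L
    id[k] <<- k; parent[k] <<- p; from[k] <<- fr; state[k] <<- s
    count[k] <<- cnt; dist[k] <<- d; members[[k]] <<- mem
    k
  }
  root_old <- old$id[old$parent == 0L]
  new_root <- add(0L, NA_character_, old$state[root_old], 1L, old$dist[root_old],
                  old$members[[root_old]])
  # queue entries: new parent id + the old child ids to merge beneath it
  queue <- list(list(p = new_root, olds = old_children[[as.character(root_old)]]))
  while (length(queue)) {
    item <- queue[[1]]; queue <- queue[-1]
    if (!length(item$olds)) next
    sts <- old$state[item$olds]
    for (s in unique(sts)) {
      grp <- item$olds[sts == s]
      k <- add(
        item$p, state[item$p], s,
        sum(old$count[grp]),
        min(old$dist[grp]),
        sort(unique(unlist(old$members[grp])))
      )
      kids <- unlist(old_children[as.character(grp)], use.names = FALSE)
      queue[[length(queue) + 1L]] <- list(p = k, olds = kids)
    }
  }
  nodes <- tibble(id = id, parent = parent, from = from, state = state,
                  count = count, dist = dist, members = members)
  new_transition_map(nodes, 2L, map$alphabet)
}

#' @rdname collapse_type2
#' @export
collapse_type3 <- function(map) {
  if (!inherits(map, "transition_map") || map$type != 2L) {
    abort("`collapse_type3()` expects a type-2 transition map.")
  }
  old <- map$nodes
  old_children <- split(old$id, factor(old$parent, levels = c(0L, old$id)))
  id <- integer(0); parent <- integer(0); from <- character(0)
  state <- character(0); count <- integer(0); dist <- numeric(0); members <- list()
  add <- function(p, fr, s, cnt, d, mem) {
    k <- length(id) + 1L
    id[k] <<- k; parent[k] <<- p; from[k] <<- fr; state[k] <<- s
    count[k] <<- cnt; dist[k] <<- d; members[[k]] <<- mem
    k
  }
  root_old <- old$id[old$parent == 0L]
  add(0L, NA_character_, old$state[root_old], 1L, old$dist[root_old],
      old$members[[root_old]])
  seen <- new.env(parent = emptyenv()) # "from|state" -> new id
  newid <- integer(nrow(old)); newid[root_old] <- 1L
  # top-down (parents before children): old ids are already in BFS-ish
  # creation order with parent < child, so ascending id order is safe
  for (v in old$id[order(old$id)]) {
    if (v == root_old) next
    key <- paste0(old$from[v], "", old$state[v])
    k <- get0(key, envir = seen)
    if (is.null(k)) {
      k <- add(newid[old$parent[v]], old$from[v], old$state[v],
               old$count[v], old$dist[v], old$members[[v]])
      assign(key, k, envir = seen)
    } else {
      count[k] <- count[k] + old$count[v]
      dist[k] <- min(dist[k], old$dist[v])
      members[[k]] <- sort(unique(c(members[[k]], old$members[[v]])))
    }
    newid[v] <- k
  }
  nodes <- tibble(id = id, parent = parent, from = from, state = state,
                  count = count, dist = dist, members = members)
  new_transition_map(nodes, 3L, map$alphabet)
}

#' Export a transition map as Newick
#'
#' Map-node labels encode state and collapse count as `state|count`; for
#' type-1 maps, branch lengths carry the distance increment between the
#' parent and child events.
#'
#' @param map A `transition_map` of any type.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
map_to_newick <- function(map, file = NULL) {
  if (!inherits(map, "transition_map")) abort("`map` must be a transition_map.")
  nd <- map$nodes
  ch <- split(nd$id, factor(nd$parent, levels = c(0L, nd$id)))
  lab <- function(v) {
    s <- paste0(nd$state[v], "|", nd$count[v])
    if (grepl("[ (),:;\\[\\]']", s)) paste0("'", gsub("'", "''", s), "'") else s
  }
  emit <- function(v) {
    kids <- ch[[as.character(v)]]
    core <- if (length(kids)) {
      paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", lab(v))
    } else {
      lab(v)
    }
    if (map$type == 1L && nd$parent[v] != 0L) {
      core <- paste0(core, ":", fmt_num(nd$dist[v] - nd$dist[nd$parent[v]]))
    }
    core
  }
  root <- nd$id[nd$parent == 0L]
  txt <- paste0(emit(root), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Transition count matrix
#'
#' @param events A `transition_events` tibble from [extract_transitions()].
#' @param alphabet Optional state ordering; defaults to the events'
#'   alphabet.
#' @return A square integer matrix of class `transition_matrix` (mode
#'   `"counts"`): cell `(i, j)` counts events `i -> j`; the diagonal is 0
#'   and the total equals the number of events.
#' @export
transition_count_matrix <- function(events, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- attr(events, "alphabet")
  if (is.null(alphabet)) alphabet <- sort(unique(c(events$from, events$to)))
  K <- length(alphabet)
  m <- matrix(0L, K, K, dimnames = list(from = alphabet, to = alphabet))
  if (nrow(events)) {
    tab <- table(factor(events$from, alphabet), factor(events$to, alphabet))
    m[] <- as.integer(tab)
  }
  structure(m, class = c("transition_matrix", class(m)), mode_label = "counts")
}

#' Relative transition rate matrix
#'
#' Fast count-based relative rates: raw counts are normalized by the total
#' event count and divided by state priors,
#' `rate(i, j) = (n_ij / N) / pi_j` by default. The `denominator` argument
#' selects which prior divides the normalized count: the target state's
#' (`"target"`, default), the source state's (`"source"`), or their product
#' (`"product"`).
#'
#' @param counts A counts-mode `transition_matrix`.
#' @param priors Named, strictly positive prior vector covering the matrix
#'   alphabet.
#' @param denominator Prior used as divisor; see Details.
#' @return A numeric `transition_matrix` with mode `"rates"`.
#' @export
relative_rate_matrix <- function(counts, priors,
                                 denominator = c("target", "source", "product")) {
  denominator <- match.arg(denominator)
  if (!identical(attr(counts, "mode_label"), "counts")) {
    abort("`counts` must be a counts-mode transition_matrix.")
  }
  alphabet <- rownames(counts)
  if (any(!alphabet %in% names(priors))) abort("Priors must cover the matrix alphabet.")
  pr <- priors[alphabet]
  if (any(pr <= 0)) abort("All priors must be strictly positive.")
  N <- sum(counts)
  if (N == 0) {
    warn("No transitions: rate matrix is all zero.", class = "traitmaps_no_events")
    rates <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    return(structure(rates, class = c("transition_matrix", "matrix", "array"),
                     mode_label = "rates"))
  }
  den <- switch(denominator,
    target = matrix(rep(pr, each = length(pr)), nrow = length(pr)),
    source = matrix(rep(pr, times = length(pr)), nrow = length(pr)),
    product = outer(pr, pr)
  )
  rates <- (unclass(counts) / N) / den
  structure(rates, class = c("transition_matrix", "matrix", "array"),
            mode_label = "rates")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> mode '%s'\n", attr(x, "mode_label")))
  print(unclass(x))
  invisible(x)
}

# ---- path queries ---------------------------------------------------------

parse_path_pattern <- function(pattern, alphabet) {
  tokens <- strsplit(trimws(pattern), "\\s+")[[1]]
  if (!length(tokens)) abort("Empty path pattern.")
  # normalize runs of consecutive wildcards
  keep <- c(TRUE, !(tokens[-1] == "*" & tokens[-length(tokens)] == "*"))
  tokens <- tokens[keep]
  bad <- setdiff(tokens, c("*", alphabet))
  if (length(bad)) {
    abort(sprintf("Pattern token(s) not in the state alphabet: %s",
                  paste(bad, collapse = ", ")))
  }
  tokens
}

# does the token sequence match a contiguous subsequence of `seq`?
# '*' matches any (possibly empty) run of states
pattern_matches <- function(seq, tokens) {
  m <- length(tokens)
  n <- length(seq)
  match_at <- function(i, k) {
    if (k > m) return(TRUE)
    if (tokens[k] == "*") {
      for (i2 in i:(n + 1L)) if (match_at(i2, k + 1L)) return(TRUE)
      return(FALSE)
    }
    if (i > n || seq[i] != tokens[k]) return(FALSE)
    match_at(i + 1L, k + 1L)
  }
  for (start in seq_len(max(n, 1L))) if (match_at(start, 1L)) return(TRUE)
  FALSE
}

#' Query root-to-leaf paths by a wildcard transition sequence
#'
#' Each root-to-leaf path is reduced to its compressed state sequence
#' (consecutive duplicates removed). A path matches when the
#' whitespace-separated pattern matches a contiguous subsequence of that
#' compressed sequence; the wildcard `*` matches any (possibly empty) run
#' of states. For example, `"A * B"` finds pathways passing from `A` to
#' `B` regardless of intermediaries.
#'
#' @inheritParams extract_transitions
#' @param pattern Pattern string, e.g. `"GREECE * ALBANIA"`.
#' @return An object of class `path_query`: `paths` (named list, matched
#'   leaf label -> root-to-leaf node id vector), `edges` (tibble `parent`,
#'   `node`, the union of matched path edges), `pattern` (normalized token
#'   vector).
#' @export
query_paths <- function(tree, states, pattern) {
  assert_phylo(tree)
  st <- full_state_vec(tree, states)
  tokens <- parse_path_pattern(pattern, sort(unique(st)))
  par <- parent_vec(tree)
  paths <- list()
  edges <- list()
  for (leaf in seq_len(ape::Ntip(tree))) {
    path <- leaf
    while (par[path[1]] != 0L) path <- c(par[path[1]], path)
    comp <- rle(st[path])$values
    if (pattern_matches(comp, tokens)) {
      paths[[tree$tip.label[leaf]]] <- path
      edges[[length(edges) + 1L]] <- tibble(parent = path[-length(path)],
                                            node = path[-1])
    }
  }
  structure(
    list(
      paths = paths,
      edges = if (length(edges)) distinct(bind_rows(edges)) else
        tibble(parent = integer(0), node = integer(0)),
      pattern = tokens
    ),
    class = "path_query"
  )
}

#' @export
print.path_query <- function(x, ...) {
  cat(sprintf(
    "<path_query> pattern [%s]: %d matching root-to-leaf path(s), %d highlighted edge(s)\n",
    paste(x$pattern, collapse = " "), length(x$paths), nrow(x$edges)
  ))
  invisible(x)
}

# ---- filters and scores ---------------------------------------------------

#' Flag nodes with ambiguous posteriors
#'
#' A node is ambiguous when at least two states have posterior probability
#' at or above the MAP probability minus `fraction` of its value, i.e.
#' `(1 - fraction) * p_max`. The retained states are exactly those meeting
#' the cutoff. The default `fraction = 0.4` retains states within 40% of
#' the MAP probability.
#'
#' @param post A [marginal_posteriors] object.
#' @param fraction Ambiguity fraction in `[0, 1]`.
#' @return A tibble `node`, `p_max`, `ambiguous`, `retained` (list of state
#'   vectors meeting the cutoff, highest probability first).
#' @export
ambiguous_nodes <- function(post, fraction = 0.4) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single number in [0, 1].")
  }
  by_node <- split(stats::setNames(post$prob, post$state), post$node)
  rows <- map(by_node, function(p) {
    pmaxv <- max(p)
    cutoff <- (1 - fraction) * pmaxv
    keep <- p >= cutoff - 1e-12
    kept <- names(sort(p[keep], decreasing = TRUE))
    list(p_max = pmaxv, ambiguous = sum(keep) >= 2L, retained = kept)
  })
  tibble(
    node = as.integer(names(by_node)),
    p_max = unname(map_dbl(rows, "p_max")),
    ambiguous = unname(map_lgl(rows, "ambiguous")),
    retained = unname(map(rows, "retained"))
  ) |> arrange(.data$node)
}

#' Descendant-size score (Sz)
#'
#' For every node, the number of leaves in its subtree annotated with the
#' node's own state (the PhyloType size criterion). A leaf scores 1.
#'
#' @inheritParams extract_transitions
#' @return A tibble `node`, `state`, `sz`.
#' @export
size_criterion <- function(tree, states) {
  assert_phylo(tree)
  st <- full_state_vec(tree, states)
  alphabet <- sort(unique(st))
  nn <- n_all_nodes(tree)
  ntip <- ape::Ntip(tree)
  counts <- matrix(0L, nn, length(alphabet), dimnames = list(NULL, alphabet))
  for (v in seq_len(ntip)) counts[v, st[v]] <- 1L
  ch <- children_list(tree)
  for (v in rev(preorder_nodes(tree))) {
    for (c_ in ch[[v]]) counts[v, ] <- counts[v, ] + counts[c_, ]
  }
  tibble(node = seq_len(nn), state = st,
         sz = counts[cbind(seq_len(nn), match(st, alphabet))])
}
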