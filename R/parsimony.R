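# Parsimony ancestral reconstruction.
#
# The workhorse is a unit-cost Sankoff dynamic program, which handles
# multifurcations natively and yields, per node, the minimum number of
# changes in its subtree conditional on each state. From it we derive:
#   - the Hartigan-style downpass set (states attaining the per-node minimum),
#   - the MPR set (states appearing in at least one globally minimal
#     labeling, via an additional outside pass),
#   - ACCTRAN / DELTRAN labelings by top-down traceback. At every node the
#     traceback chooses among the states that keep the global score minimal;
#     ACCTRAN prefers a state different from the parent (changes pulled
#     rootward), DELTRAN prefers the parent's state (changes pushed tipward),
#     and remaining ties are broken lexicographically.

# per-node Sankoff cost matrix (nodes x states); missing tips cost 0 everywhere
sankoff_costs <- function(tree, tipst, alphabet) {
  K <- length(alphabet)
  nn <- n_all_nodes(tree)
  ntip <- ape::Ntip(tree)
  big <- n_all_nodes(tree) + 1
  cost <- matrix(0, nrow = nn, ncol = K)
  for (v in seq_len(ntip)) {
    if (!is.na(tipst[v])) {
      cost[v, ] <- big
      cost[v, match(tipst[v], alphabet)] <- 0
    }
  }
  ch <- children_list(tree)
  for (v in rev(preorder_nodes(tree))) {
    kids <- ch[[v]]
    if (!length(kids)) next
    for (c_ in kids) {
      inc <- pmin(cost[c_, ], min(cost[c_, ]) + 1)
      cost[v, ] <- cost[v, ] + inc
    }
  }
  cost
}

#' Fitch/Hartigan downpass state sets and parsimony score
#'
#' Computes, for every node, the set of states attaining the minimum number
#' of changes within that node's subtree (the downpass set, Hartigan's
#' generalization for multifurcating trees), and the overall minimum change
#' count (parsimony score). Branch lengths are ignored. Tips with missing
#' annotation carry the full alphabet.
#'
#' @param tree A rooted `phylo` tree.
#' @param data A [character_data] tip annotation set.
#' @return A list with `sets` (list of character vectors indexed by node id),
#'   `score` (integer minimum change count) and `cost` (the per-node,
#'   per-state Sankoff cost matrix, ordered by the alphabet).
#' @export
fitch_downpass <- function(tree, data) {
  assert_phylo(tree)
  alphabet <- state_alphabet(data)
  tipst <- tip_states(tree, data)
  if (all(is.na(tipst))) abort("character uninformative: every leaf annotation is missing")
  cost <- sankoff_costs(tree, tipst, alphabet)
  sets <- lapply(seq_len(nrow(cost)), function(v) {
    alphabet[cost[v, ] == min(cost[v, ])]
  })
  score <- as.integer(min(cost[root_node(tree), ]))
  list(sets = sets, score = score, cost = cost, alphabet = alphabet)
}

# outside cost o[v, s]: minimal number of changes outside v's subtree given
# state(v) = s; MPR set of v = { s : cost[v,s] + o[v,s] == score }
mpr_sets <- function(tree, cost, alphabet) {
  nn <- nrow(cost)
  K <- ncol(cost)
  ch <- children_list(tree)
  par <- parent_vec(tree)
  o <- matrix(0, nrow = nn, ncol = K)
  pre <- preorder_nodes(tree)
  for (v in pre) {
    p <- par[v]
    if (p == 0L) next
    # "above" cost of the parent conditional on parent state r:
    # o[p, r] + sum over siblings of min(cost[sib, r], min cost[sib] + 1)
    above <- o[p, ]
    for (w in ch[[p]]) {
      if (w == v) next
      above <- above + pmin(cost[w, ], min(cost[w, ]) + 1)
    }
    # child state s: parent may take any r, paying 1 if r != s
    o[v, ] <- vapply(seq_len(K), function(s) {
      min(above + (seq_len(K) != s))
    }, numeric(1))
  }
  score <- min(cost[root_node(tree), ])
  lapply(seq_len(nn), function(v) alphabet[cost[v, ] + o[v, ] == score])
}

parsimony_traceback <- function(tree, cost, alphabet, prefer_change) {
  nn <- nrow(cost)
  par <- parent_vec(tree)
  state <- character(nn)
  for (v in preorder_nodes(tree)) {
    p <- par[v]
    if (p == 0L) {
      cand <- alphabet[cost[v, ] == min(cost[v, ])]
      state[v] <- cand[1] # lexicographic: alphabet is sorted
      next
    }
    ps <- state[p]
    tot <- cost[v, ] + (alphabet != ps)
    cand <- alphabet[tot == min(tot)]
    if (length(cand) > 1L) {
      if (prefer_change && any(cand != ps)) cand <- cand[cand != ps]
      if (!prefer_change && ps %in% cand) cand <- ps
    }
    state[v] <- cand[1]
  }
  state
}

parsimony_fit <- function(tree, data, method) {
  dp <- fitch_downpass(tree, data)
  states <- parsimony_traceback(tree, dp$cost, dp$alphabet,
                                prefer_change = (method == "acctran"))
  structure(
    list(
      states = node_states(seq_along(states), states, tree),
      downpass = dp$sets,
      mpr = mpr_sets(tree, dp$cost, dp$alphabet),
      score = dp$score,
      method = method,
      alphabet = dp$alphabet
    ),
    class = "parsimony_fit"
  )
}

#' Parsimony reconstruction with ACCTRAN / DELTRAN resolution
#'
#' Both return a single-state-per-node labeling realizing the minimum change
#' count. `acctran()` resolves ambiguity by accelerating changes toward the
#' root (a change is preferred whenever it keeps the score minimal);
#' `deltran()` delays changes toward the tips (the parent's state is kept
#' whenever admissible). Remaining ties are broken lexicographically.
#'
#' @inheritParams fitch_downpass
#' @return A `parsimony_fit` object: `states` (tibble `node`, `state`),
#'   `downpass` and `mpr` state-set lists, `score`, `method`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' cd <- character_data(c("A", "B", "C"), c("red", "blue", "blue"))
#' acctran(tr, cd)$score
#' @export
acctran <- function(tree, data) parsimony_fit(tree, data, "acctran")

#' @rdname acctran
#' @export
deltran <- function(tree, data) parsimony_fit(tree, data, "deltran")

#' @export
print.parsimony_fit <- function(x, ...) {
  cat(sprintf(
    "<parsimony_fit> %s: score %d over %d nodes, alphabet {%s}\n",
    toupper(x$method), x$score, nrow(x$states),
    paste(x$alphabet, collapse = ", ")
  ))
  invisible(x)
}

# number of edges whose endpoint states differ under a full labeling
realized_changes <- function(tree, states) {
  st <- states$state[order(states$node)]
  sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
}
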