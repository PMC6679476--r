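# Seeded synthetic data: Yule trees, F81 character evolution, and the
# worked-example fixture with a known transition multiset.

#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation: the root splits into two lineages at time 0; while
#' `k < n` lineages are extant, a waiting time `Exp(k * birth)` elapses (all
#' extant branches grow by it) and one uniformly chosen lineage splits; a
#' final `Exp(n * birth)` waiting time is drawn after the last split so tips
#' end on a common horizon. The root-to-tip height is therefore
#' `sum_{k=2..n} Exp(k * birth)`, with mean `(1/birth) * sum_{k=2..n} 1/k`.
#'
#' @param n Number of tips (>= 2).
#' @param birth Birth rate (per lineage, per unit time).
#' @param seed Optional seed; a fixed seed gives a byte-identical tree.
#' @return An ultrametric binary `phylo` tree with tips `t1..tn`.
#' @export
sim_yule_tree <- function(n, birth = 1, seed = NULL) {
  if (n < 2) abort("`n` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  parent <- c(0L, 1L, 1L)
  length_ <- c(0, 0, 0)
  active <- c(2L, 3L)
  k <- 2L
  while (k < n) {
    w <- stats::rexp(1, rate = k * birth)
    length_[active] <- length_[active] + w
    split <- active[sample.int(k, 1)]
    m <- base::length(parent)
    parent <- c(parent, split, split)
    length_ <- c(length_, 0, 0)
    active <- c(setdiff(active, split), m + 1L, m + 2L)
    k <- k + 1L
  }
  w <- stats::rexp(1, rate = n * birth)
  length_[active] <- length_[active] + w

  kids <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
  tip_no <- 0L
  emit <- function(v) {
    ch <- kids[[v]]
    if (length(ch)) {
      inner <- paste(vapply(ch, emit, character(1)), collapse = ",")
      core <- paste0("(", inner, ")")
    } else {
      tip_no <<- tip_no + 1L
      core <- paste0("t", tip_no)
    }
    if (parent[v] == 0L) core else paste0(core, ":", format(length_[v], digits = 15))
  }
  parse_quiet(paste0(emit(1L), ";"))
}

#' Simulate a discrete character along a tree under the F81-like model
#'
#' The root state is drawn from the model's priors; each edge then evolves
#' by the model's transition probability for its (sigma-scaled) length.
#' Returns both the observable tip annotations and the true states of every
#' node, so parameter- and state-recovery can be scored.
#'
#' @param tree A rooted `phylo` tree (branch lengths required; `sigma = 0`
#'   in the model is allowed and freezes the root state everywhere).
#' @param model An [f81_model]; its `sigma` scales the branch lengths.
#' @param seed Optional seed for reproducibility.
#' @param name Character name for the returned [character_data].
#' @return A list: `tips` (a [character_data] over the tree's tips) and
#'   `truth` (tibble `node`, `state` for every node).
#' @export
simulate_character <- function(tree, model, seed = NULL, name = "trait") {
  assert_phylo(tree)
  if (!is.null(seed)) set.seed(seed)
  sigma0 <- model$sigma == 0
  nn <- n_all_nodes(tree)
  len <- edge_length_vec(tree)
  len[is.na(len)] <- 0
  par <- parent_vec(tree)
  alphabet <- model$alphabet
  st <- character(nn)
  r <- root_node(tree)
  st[r] <- sample(alphabet, 1, prob = model$pi)
  if (!sigma0) {
    # cache transition matrices per distinct length
    P_cache <- new.env(parent = emptyenv())
    for (v in preorder_nodes(tree)) {
      if (par[v] == 0L) next
      key <- format(len[v], digits = 15)
      P <- get0(key, envir = P_cache)
      if (is.null(P)) {
        P <- f81_transition_probability(model, len[v])
        assign(key, P, envir = P_cache)
      }
      st[v] <- sample(alphabet, 1, prob = P[st[par[v]], ])
    }
  } else {
    st[] <- st[r]
  }
  tips <- character_data(tree$tip.label, st[seq_len(ape::Ntip(tree))],
                         name = name, alphabet = alphabet)
  list(tips = tips, truth = node_states(seq_len(nn), st, tree))
}

#' Worked-example fixture: annotated tree with a known transition multiset
#'
#' A fully annotated tree over three states (gray, red, gold) whose
#' transition multiset is exactly `{gray->red x2, gray->gold x1,
#' red->gold x1}`, with both gray->red events attached directly under the
#' map root. Node `t1` is a red cherry holding one red and one gold leaf
#' (so its same-state descendant score Sz is 1); `t2` is an all-red cherry;
#' two gray leaves sit directly under the gray root. All branch lengths are
#' 1 and the annotation is parsimony-consistent: the minimum change count
#' of the tip states equals the four realized events.
#'
#' @return A list: `tree` (a `phylo`), `states` (tibble `node`, `state`
#'   covering every node), `tips` (the tip annotations as
#'   [character_data]).
#' @export
fig3_fixture <- function() {
  tree <- parse_quiet(
    "(G0:1,G1:1,(L1:1,L2:1)t1:1,(L3:1,L4:1)t2:1,L5:1)root;"
  )
  tip_state <- c(G0 = "gray", G1 = "gray", L1 = "red", L2 = "gold",
                 L3 = "red", L4 = "red", L5 = "gold")
  lab <- node_labels(tree)
  internal_state <- c(root = "gray", t1 = "red", t2 = "red")
  st <- character(n_all_nodes(tree))
  st[seq_len(ape::Ntip(tree))] <- tip_state[tree$tip.label]
  idx <- (ape::Ntip(tree) + 1L):n_all_nodes(tree)
  st[idx] <- internal_state[lab[idx]]
  list(
    tree = tree,
    states = node_states(seq_along(st), st, tree),
    tips = character_data(names(tip_state), unname(tip_state), name = "shape")
  )
}
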