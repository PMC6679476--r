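# Independent oracles used across the suite. Everything here deliberately
# avoids the package's own algorithms: brute-force enumeration over all
# internal labelings, direct probability sums, and regex matching.

# random binary fixture tree; lengths ~ Yule waiting times
random_tree <- function(n, seed) sim_yule_tree(n, seed = seed)

# random fixture tree, sometimes multifurcating (short internal edges
# collapsed), with iid random tip states over K states
random_annotated_tips <- function(n, K, seed, p_multi = 0.3) {
  tr <- sim_yule_tree(n, seed = seed)
  set.seed(seed + 10000L)
  if (stats::runif(1) < p_multi && !is.null(tr$edge.length)) {
    q <- stats::quantile(tr$edge.length, 0.2)
    tr <- ape::di2multi(tr, tol = q)
  }
  states <- paste0("s", seq_len(K))
  tips <- character_data(tr$tip.label, sample(states, ape::Ntip(tr), TRUE),
                         alphabet = states)
  list(tree = tr, tips = tips)
}

# full random annotation of every node (for transition-analysis fixtures)
random_full_annotation <- function(tree, K, seed) {
  set.seed(seed)
  states <- paste0("s", seq_len(K))
  nn <- ape::Ntip(tree) + tree$Nnode
  node_states(seq_len(nn), sample(states, nn, TRUE), tree)
}

# enumerate all assignments of `alphabet` to the internal nodes; tips fixed
# (NA tips range over the alphabet too)
enumerate_assignments <- function(tree, tipst, alphabet) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  free <- c(which(is.na(tipst)), (ntip + 1L):nn)
  grids <- rep(list(alphabet), length(free))
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  base <- rep(NA_character_, nn)
  base[seq_len(ntip)] <- tipst
  lapply(seq_len(nrow(grid)), function(i) {
    st <- base
    st[free] <- as.character(grid[i, ])
    st
  })
}

count_changes <- function(tree, st) {
  sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
}

# brute-force minimum parsimony score
brute_parsimony_min <- function(tree, tips) {
  tipst <- tip_states(tree, tips)
  asg <- enumerate_assignments(tree, tipst, state_alphabet(tips))
  min(vapply(asg, function(st) count_changes(tree, st), numeric(1)))
}

# direct probability of one full assignment under the F81-like model
assignment_prob <- function(tree, st, model) {
  len <- tree$edge.length
  if (is.null(len)) len <- rep(0, nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  p <- model$pi[match(st[root], model$alphabet)]
  for (i in seq_len(nrow(tree$edge))) {
    P <- f81_transition_probability(model, len[i])
    p <- p * P[st[tree$edge[i, 1]], st[tree$edge[i, 2]]]
  }
  p
}

# exhaustive-sum likelihood and per-node marginal posteriors
brute_likelihood <- function(tree, tips, model) {
  tipst <- tip_states(tree, tips)
  asg <- enumerate_assignments(tree, tipst, model$alphabet)
  probs <- vapply(asg, function(st) assignment_prob(tree, st, model), numeric(1))
  nn <- ape::Ntip(tree) + tree$Nnode
  K <- length(model$alphabet)
  post <- matrix(0, nn, K, dimnames = list(NULL, model$alphabet))
  for (i in seq_along(asg)) {
    idx <- cbind(seq_len(nn), match(asg[[i]], model$alphabet))
    post[idx] <- post[idx] + probs[i]
  }
  list(lik = sum(probs), post = post / sum(probs), probs = probs, asg = asg)
}

# exhaustive joint argmax (lexicographic tie-break to mirror the package)
brute_joint <- function(tree, tips, model) {
  br <- brute_likelihood(tree, tips, model)
  keys <- vapply(br$asg, paste, character(1), collapse = "\r")
  ord <- order(-br$probs, keys)
  list(states = br$asg[[ord[1]]], prob = br$probs[ord[1]])
}

# regex oracle for wildcard path queries: states mapped to single letters
regex_query_oracle <- function(tree, states, pattern) {
  st <- as_node_states(states)
  stv <- st$state[order(st$node)]
  alphabet <- sort(unique(stv))
  letter <- stats::setNames(letters[seq_along(alphabet)], alphabet)
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  tokens <- strsplit(trimws(pattern), "\\s+")[[1]]
  rx <- paste(vapply(tokens, function(t) {
    if (t == "*") ".*" else letter[[t]]
  }, character(1)), collapse = "")
  hits <- character(0)
  for (leaf in seq_len(ape::Ntip(tree))) {
    path <- leaf
    while (par[path[1]] != 0L) path <- c(par[path[1]], path)
    comp <- rle(stv[path])$values
    if (grepl(rx, paste(letter[comp], collapse = ""))) {
      hits <- c(hits, tree$tip.label[leaf])
    }
  }
  sort(hits)
}

# independent contraction of state-constant edges: returns the set of
# (event node, nearest ancestral event node or root) pairs
contract_oracle <- function(tree, states) {
  stv <- as_node_states(states)$state
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  par <- integer(nn)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  rep_ <- integer(nn)
  # preorder via repeated sweeps (small trees only)
  ord <- root
  while (length(ord) < nn) {
    ord <- c(ord, tree$edge[tree$edge[, 1] %in% ord & !tree$edge[, 2] %in% ord, 2])
  }
  pairs <- list()
  for (v in ord) {
    if (v == root) { rep_[v] <- root; next }
    if (stv[v] != stv[par[v]]) {
      rep_[v] <- v
      pairs[[length(pairs) + 1L]] <- c(rep_[par[v]], v)
    } else rep_[v] <- rep_[par[v]]
  }
  pairs
}

expect_same_tree <- function(a, b) {
  expect_identical(ape::Ntip(a), ape::Ntip(b))
  expect_identical(a$tip.label, b$tip.label)
  expect_equal(a$edge, b$edge)
  if (is.null(a$edge.length)) expect_null(b$edge.length)
  else expect_equal(a$edge.length, b$edge.length, tolerance = 1e-8)
}
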