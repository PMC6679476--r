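# F81-like maximum-likelihood ancestral reconstruction.
#
# Model: continuous-time substitution with stationary state frequencies pi;
# the probability of ending in state j after a branch of scaled length t is
#     P(i -> j | t) = pi_j (1 - exp(-mu sigma t)) + [i == j] exp(-mu sigma t)
# with the normalization rate mu = 1 / (1 - sum_s pi_s^2) (so that one time
# unit corresponds to one expected substitution at stationarity) and a single
# free scaling factor sigma > 0 applied to every branch, fitted by maximum
# likelihood. The model is time-reversible: pi_i P(i->j|t) = pi_j P(j->i|t).

#' Estimate state priors from tip annotations
#'
#' Observed leaf frequencies with add-one (Laplace) smoothing over the
#' alphabet, so every prior is strictly positive as the F81-like model
#' requires: `pi_s = (n_s + 1) / (n + K)`.
#'
#' @param data A [character_data] annotation set with at least one
#'   non-missing state.
#' @param smoothing Pseudo-count added per state (default 1; 0 gives raw
#'   frequencies, which may contain zeros).
#' @return Named numeric vector of priors over the alphabet, summing to 1.
#' @export
estimate_priors <- function(data, smoothing = 1) {
  alphabet <- state_alphabet(data)
  obs <- data$state[!is.na(data$state)]
  if (!length(obs)) abort("Cannot estimate priors: no annotated leaves.")
  counts <- table(factor(obs, levels = alphabet))
  pi <- (as.numeric(counts) + smoothing) / (length(obs) + smoothing * length(alphabet))
  stats::setNames(pi, alphabet)
}

#' F81-like model object
#'
#' @param priors Named numeric vector of strictly positive state priors
#'   summing to 1 (names are the state alphabet).
#' @param sigma Branch-length scaling factor (> 0).
#' @param loglik Optional maximized log-likelihood to store.
#' @return An object of class `f81_model` with fields `alphabet`, `pi`,
#'   `mu` (= `1 / (1 - sum(pi^2))`), `sigma`, `loglik`.
#' @export
f81_model <- function(priors, sigma = 1, loglik = NA_real_) {
  if (is.null(names(priors)) || any(!nzchar(names(priors)))) {
    abort("`priors` must be a named vector (names = state alphabet).")
  }
  if (any(priors <= 0)) abort("All priors must be strictly positive.")
  if (abs(sum(priors) - 1) > 1e-8) abort("Priors must sum to 1.")
  if (length(priors) < 2L) abort("The model needs an alphabet of at least 2 states.")
  if (sigma < 0) abort("`sigma` must be nonnegative.")
  o <- order(names(priors))
  priors <- priors[o]
  structure(
    list(
      alphabet = names(priors),
      pi = as.numeric(priors),
      mu = 1 / (1 - sum(priors^2)),
      sigma = sigma,
      loglik = loglik
    ),
    class = "f81_model"
  )
}

#' @export
print.f81_model <- function(x, ...) {
  cat(sprintf(
    "<f81_model> %d states, mu = %.4f, sigma = %.6g, logL = %s\n",
    length(x$alphabet), x$mu, x$sigma,
    if (is.na(x$loglik)) "NA" else sprintf("%.4f", x$loglik)
  ))
  cat("  priors:", paste(sprintf("%s=%.4f", x$alphabet, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' F81 transition probability matrix
#'
#' @param model An [f81_model].
#' @param length Branch length (unscaled, >= 0); the model's `sigma` and
#'   `mu` are applied internally. A zero length gives the identity matrix.
#' @return A row-stochastic state-by-state matrix with `pi` as stationary
#'   distribution.
#' @export
f81_transition_probability <- function(model, length) {
  if (length < 0) abort("Branch length must be >= 0.")
  K <- base::length(model$pi)
  e <- exp(-model$mu * model$sigma * length)
  P <- matrix(rep(model$pi * (1 - e), each = K), nrow = K)
  diag(P) <- diag(P) + e
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

# per-tip likelihood row: one-hot for an observed state, all-ones for missing
tip_partial <- function(tipst, alphabet) {
  K <- length(alphabet)
  t(vapply(tipst, function(s) {
    if (is.na(s)) rep(1, K) else as.numeric(alphabet == s)
  }, numeric(K)))
}

# Felsenstein pruning with per-node renormalization; returns the per-node
# conditional likelihood matrix L (rescaled), the per-node accumulated log
# scalers, and the tree log-likelihood.
pruning_pass <- function(tree, tipst, model) {
  alphabet <- model$alphabet
  K <- length(alphabet)
  nn <- n_all_nodes(tree)
  ntip <- ape::Ntip(tree)
  L <- matrix(1, nrow = nn, ncol = K)
  L[seq_len(ntip), ] <- tip_partial(tipst, alphabet)
  logscale <- numeric(nn)
  len <- edge_length_vec(tree)
  len[is.na(len)] <- 0
  ch <- children_list(tree)
  for (v in rev(preorder_nodes(tree))) {
    kids <- ch[[v]]
    if (!length(kids)) next
    for (c_ in kids) {
      P <- f81_transition_probability(model, len[c_])
      L[v, ] <- L[v, ] * as.numeric(P %*% L[c_, ])
      logscale[v] <- logscale[v] + logscale[c_]
    }
    m <- sum(L[v, ])
    if (m > 0 && is.finite(m)) {
      L[v, ] <- L[v, ] / m
      logscale[v] <- logscale[v] + log(m)
    }
  }
  r <- root_node(tree)
  lik <- sum(model$pi * L[r, ])
  loglik <- if (lik > 0) log(lik) + logscale[r] else -Inf
  list(L = L, logscale = logscale, loglik = loglik, lengths = len)
}

#' Tree log-likelihood under the F81-like model
#'
#' Felsenstein-pruning log-likelihood of the tip annotations, with the root
#' weighted by the stationary priors. Tips with missing annotation integrate
#' over all states. Conflicting states across zero-length branches yield
#' `-Inf` rather than an error.
#'
#' @param tree A rooted `phylo` tree.
#' @param data A [character_data] annotation set.
#' @param model An [f81_model] whose alphabet covers the data's.
#' @return The log-likelihood (scalar; `-Inf` for impossible data).
#' @export
tree_log_likelihood <- function(tree, data, model) {
  assert_phylo(tree)
  check_model_covers(model, data)
  pruning_pass(tree, tip_states(tree, data), model)$loglik
}

check_model_covers <- function(model, data) {
  extra <- setdiff(state_alphabet(data), model$alphabet)
  if (length(extra)) {
    abort(sprintf("Model alphabet lacks state(s): %s", paste(extra, collapse = ", ")))
  }
}

#' Fit the global branch-length scaling factor by maximum likelihood
#'
#' Branch lengths (typically in substitutions/site from sequence data) are
#' rescaled by a single factor `sigma` so they fit the evolutionary rate of
#' the analyzed character; `sigma` is chosen to maximize the pruning
#' likelihood by Brent search on `log(sigma)` over `[log 1e-3, log 1e3]`
#' (tolerance 1e-6 in log space). With fewer than two distinct observed
#' states the factor is unidentifiable: `sigma = 1` is returned with a
#' warning. Trees without branch lengths get unit lengths (with a warning);
#' `sigma` then absorbs the unit.
#'
#' @inheritParams tree_log_likelihood
#' @param priors Named prior vector; default [estimate_priors] on `data`.
#' @param interval Log-scale search interval for `sigma`.
#' @return An [f81_model] with `sigma` and `loglik` filled in.
#' @export
fit_scaling_factor <- function(tree, data, priors = NULL,
                               interval = log(c(1e-3, 1e3))) {
  assert_phylo(tree)
  if (is.null(priors)) priors <- estimate_priors(data)
  tree <- ensure_branch_lengths(tree)
  obs <- unique(data$state[!is.na(data$state)])
  if (length(obs) < 2L) {
    warn("Fewer than two observed states: scaling factor is unidentifiable; using sigma = 1.",
         class = "traitmaps_sigma_unidentifiable")
    m <- f81_model(priors, sigma = 1)
    m$loglik <- tree_log_likelihood(tree, data, m)
    return(m)
  }
  tipst <- tip_states(tree, data)
  obj <- function(logsig) {
    m <- f81_model(priors, sigma = exp(logsig))
    ll <- pruning_pass(tree, tipst, m)$loglik
    if (!is.finite(ll)) -1e300 else ll
  }
  fit <- stats::optimize(obj, interval = interval, maximum = TRUE, tol = 1e-6)
  if (fit$objective <= -1e299) {
    abort("Likelihood is non-finite across the whole sigma search interval.")
  }
  if (min(abs(fit$maximum - interval)) < 1e-3) {
    warn("Fitted sigma lies at the search bound; the data may be uninformative about the rate.",
         class = "traitmaps_sigma_at_bound")
  }
  f81_model(priors, sigma = exp(fit$maximum), loglik = fit$objective)
}

ensure_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    warn("Tree has no branch lengths; using unit lengths (sigma absorbs the unit).",
         class = "traitmaps_unit_lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Marginal posterior state probabilities at every node
#'
#' One bottom-up (pruning) pass and one top-down (outside) pass; the
#' posterior at a node is proportional to the product of its inside and
#' outside likelihoods. Each node's probabilities sum to 1; an annotated
#' leaf's posterior is a point mass on its observed state.
#'
#' @inheritParams tree_log_likelihood
#' @return An object of class `marginal_posteriors`: a long tibble `node`,
#'   `state`, `prob`, with the model's log-likelihood in
#'   `attr(, "loglik")`.
#' @export
marginal_posteriors <- function(tree, data, model) {
  assert_phylo(tree)
  check_model_covers(model, data)
  tipst <- tip_states(tree, data)
  up <- pruning_pass(tree, tipst, model)
  if (!is.finite(up$loglik)) {
    abort("Data have zero likelihood under the model; posteriors undefined.")
  }
  alphabet <- model$alphabet
  K <- length(alphabet)
  nn <- n_all_nodes(tree)
  ch <- children_list(tree)
  par <- parent_vec(tree)
  D <- matrix(0, nrow = nn, ncol = K) # outside (renormalized each node)
  r <- root_node(tree)
  D[r, ] <- model$pi
  for (v in preorder_nodes(tree)) {
    p <- par[v]
    if (p == 0L) next
    above <- D[p, ]
    for (w in ch[[p]]) {
      if (w == v) next
      Pw <- f81_transition_probability(model, up$lengths[w])
      above <- above * as.numeric(Pw %*% up$L[w, ])
    }
    Pv <- f81_transition_probability(model, up$lengths[v])
    D[v, ] <- as.numeric(above %*% Pv)
    s <- sum(D[v, ])
    if (s > 0) D[v, ] <- D[v, ] / s
  }
  post <- up$L * D
  rs <- rowSums(post)
  post <- post / ifelse(rs > 0, rs, 1)
  out <- tibble(
    node = rep(seq_len(nn), each = K),
    state = rep(alphabet, times = nn),
    prob = as.numeric(t(post))
  )
  attr(out, "loglik") <- up$loglik
  attr(out, "alphabet") <- alphabet
  class(out) <- c("marginal_posteriors", class(out))
  out
}

#' MAP states from marginal posteriors
#'
#' Per node, the state maximizing the marginal posterior; exact ties are
#' broken lexicographically and flagged.
#'
#' @param post A [marginal_posteriors] object.
#' @return A tibble `node`, `state`, `tie` (logical).
#' @export
map_states <- function(post) {
  by_node <- split(stats::setNames(post$prob, post$state), post$node)
  picks <- map(by_node, majority_state)
  tibble(
    node = as.integer(names(by_node)),
    state = unname(map_chr(picks, as.character)),
    tie = unname(map_lgl(picks, ~ isTRUE(attr(.x, "tie"))))
  ) |> arrange(.data$node)
}

#' Jointly most likely ancestral reconstruction
#'
#' Max-product dynamic programming over the tree (bottom-up tables with
#' back-pointers, then a top-down traceback) returning the single full
#' assignment of states to nodes with the highest joint probability, and
#' that log-probability. Ties are broken lexicographically.
#'
#' @inheritParams tree_log_likelihood
#' @return An object of class `joint_fit`: `states` (tibble `node`,
#'   `state`), `log_prob`, `method = "joint"`.
#' @export
joint_reconstruction <- function(tree, data, model) {
  assert_phylo(tree)
  check_model_covers(model, data)
  tipst <- tip_states(tree, data)
  alphabet <- model$alphabet
  K <- length(alphabet)
  nn <- n_all_nodes(tree)
  ntip <- ape::Ntip(tree)
  len <- edge_length_vec(tree)
  len[is.na(len)] <- 0
  ch <- children_list(tree)
  # C[v, r]: max log-prob of v's subtree (including the edge into v) given
  # the parent is in state r; B[v, r]: the argmax state of v
  C <- matrix(0, nrow = nn, ncol = K)
  B <- matrix(0L, nrow = nn, ncol = K)
  # inside max log-prob of the subtree below v given v's own state
  M <- matrix(0, nrow = nn, ncol = K)
  for (v in seq_len(ntip)) {
    if (!is.na(tipst[v])) M[v, ] <- ifelse(alphabet == tipst[v], 0, -Inf)
  }
  for (v in rev(preorder_nodes(tree))) {
    kids <- ch[[v]]
    if (length(kids)) {
      M[v, ] <- 0
      for (c_ in kids) M[v, ] <- M[v, ] + C[c_, ]
    }
    logP <- log(f81_transition_probability(model, len[v]))
    for (r in seq_len(K)) {
      tot <- logP[r, ] + M[v, ]
      best <- which(tot == max(tot))[1] # alphabet sorted => lexicographic
      C[v, r] <- tot[best]
      B[v, r] <- best
    }
  }
  r_ <- root_node(tree)
  root_tot <- log(model$pi) + M[r_, ]
  states <- integer(nn)
  states[r_] <- which(root_tot == max(root_tot))[1]
  par <- parent_vec(tree)
  for (v in preorder_nodes(tree)) {
    if (par[v] == 0L) next
    states[v] <- B[v, states[par[v]]]
  }
  structure(
    list(
      states = node_states(seq_len(nn), alphabet[states], tree),
      log_prob = max(root_tot),
      method = "joint",
      alphabet = alphabet
    ),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf(
    "<joint_fit> most likely assignment over %d nodes, log-probability %.4f\n",
    nrow(x$states), x$log_prob
  ))
  invisible(x)
}
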