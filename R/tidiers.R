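#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy / glance methods for fitted objects
#'
#' `tidy()` returns the per-element detail of an object (per-state priors,
#' per-node states, map nodes, matrix cells); `glance()` returns a one-row
#' summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name traitmaps-tidiers
NULL

#' @rdname traitmaps-tidiers
#' @export
tidy.f81_model <- function(x, ...) {
  tibble(state = x$alphabet, prior = x$pi)
}

#' @rdname traitmaps-tidiers
#' @export
glance.f81_model <- function(x, ...) {
  tibble(n_states = length(x$alphabet), mu = x$mu, sigma = x$sigma,
         loglik = x$loglik)
}

#' @rdname traitmaps-tidiers
#' @export
tidy.parsimony_fit <- function(x, ...) {
  mutate(x$states,
         downpass = x$downpass[.data$node],
         mpr = x$mpr[.data$node],
         ambiguous = lengths(x$mpr[.data$node]) > 1L)
}

#' @rdname traitmaps-tidiers
#' @export
glance.parsimony_fit <- function(x, ...) {
  tibble(method = x$method, score = x$score, n_nodes = nrow(x$states))
}

#' @rdname traitmaps-tidiers
#' @export
tidy.joint_fit <- function(x, ...) x$states

#' @rdname traitmaps-tidiers
#' @export
glance.joint_fit <- function(x, ...) {
  tibble(method = "joint", log_prob = x$log_prob, n_nodes = nrow(x$states))
}

#' @rdname traitmaps-tidiers
#' @export
tidy.transition_map <- function(x, ...) {
  mutate(x$nodes, n_members = lengths(.data$members))
}

#' @rdname traitmaps-tidiers
#' @export
glance.transition_map <- function(x, ...) {
  tibble(type = x$type, n_nodes = nrow(x$nodes),
         n_transitions = sum(x$nodes$count[x$nodes$parent != 0L]))
}

#' @rdname traitmaps-tidiers
#' @export
tidy.transition_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    mode = attr(x, "mode_label")
  )
}

#' @rdname traitmaps-tidiers
#' @export
tidy.comparison <- function(x, ...) x$table

#' @rdname traitmaps-tidiers
#' @export
glance.comparison <- function(x, ...) {
  tibble(methods = paste(x$methods, collapse = ","),
         n_compared = nrow(x$table), n_discrepant = x$n_discrepant)
}
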