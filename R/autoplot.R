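#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_text
#'   geom_tile scale_size_area labs theme_minimal theme element_blank
#'   scale_fill_gradient coord_equal
#' @export
ggplot2::autoplot

#' Plot a transition map
#'
#' Tree-like ggplot of a transition map: nodes sized by collapse count and
#' colored by state, x positioned by cumulative distance (type 1) or map
#' depth (types 2-3).
#'
#' @param object A `transition_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_map <- function(object, ...) {
  nd <- object$nodes
  nlev <- integer(nrow(nd))
  for (v in nd$id) nlev[v] <- if (nd$parent[v] == 0L) 0L else nlev[nd$parent[v]] + 1L
  xv <- if (object$type == 1L) nd$dist else as.numeric(nlev)
  ch <- split(nd$id, factor(nd$parent, levels = c(0L, nd$id)))
  ypos <- numeric(nrow(nd)); rank <- 0
  assign_y <- function(v) {
    kids <- ch[[as.character(v)]]
    if (!length(kids)) { rank <<- rank + 1; ypos[v] <<- rank }
    else { for (k in kids) assign_y(k); ypos[v] <<- mean(ypos[kids]) }
  }
  assign_y(nd$id[nd$parent == 0L])
  df <- mutate(nd, x = xv, y = ypos,
               label = sprintf("%s|%d", .data$state, .data$count))
  seg <- filter(df, .data$parent != 0L) |>
    mutate(xend = df$x[.data$parent], yend = df$y[.data$parent])
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = seg,
                 aes(xend = .data$xend, yend = .data$yend), color = "grey60") +
    geom_point(aes(size = .data$count, color = .data$state)) +
    geom_text(aes(label = .data$label), hjust = -0.2, vjust = -0.6, size = 3) +
    scale_size_area(max_size = 12) +
    labs(x = if (object$type == 1L) "distance to root" else "map depth",
         y = NULL, title = sprintf("Transition map (type %d)", object$type)) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid.major.y = element_blank())
}

#' Heatmap of marginal posteriors
#'
#' @param object A [marginal_posteriors] object.
#' @param ... Unused.
#' @return A ggplot object (node x state tile map of posterior probability).
#' @export
autoplot.marginal_posteriors <- function(object, ...) {
  ggplot(object, aes(x = .data$state, y = factor(.data$node),
                     fill = .data$prob)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#2c7fb8", limits = c(0, 1)) +
    labs(x = "state", y = "node", fill = "posterior") +
    theme_minimal()
}

#' Tile plot of a transition matrix
#'
#' @param object A `transition_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy.transition_matrix(object)
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$value)) +
    geom_tile(color = "grey80") +
    geom_text(aes(label = signif(.data$value, 3)), size = 3) +
    scale_fill_gradient(low = "white", high = "#de2d26") +
    coord_equal() +
    labs(title = sprintf("Transition %s", attr(object, "mode_label"))) +
    theme_minimal()
}
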