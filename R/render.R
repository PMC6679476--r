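# Deterministic SVG output for annotated trees and transition maps.
#
# The writer emits plain SVG 1.1 text (one element per line, fixed numeric
# formatting), so identical inputs produce byte-identical files.

#' Rendering options
#'
#' @param layout `"rectangular"`, `"slanted"` or `"radial"`.
#' @param colors Named character vector, state -> SVG color. States without
#'   an entry are auto-assigned from a fixed 20-color palette.
#' @param pies Draw posterior pie charts at ambiguous nodes (needs
#'   posteriors at render time).
#' @param fraction Ambiguity fraction passed to [ambiguous_nodes()].
#' @param shade_sz Shade node backgrounds by the descendant-size score.
#' @param width,height Canvas size in pixels.
#' @return A list of class `render_options`.
#' @export
render_options <- function(layout = c("rectangular", "slanted", "radial"),
                           colors = character(), pies = FALSE, fraction = 0.4,
                           shade_sz = FALSE, width = 800, height = 600) {
  layout <- match.arg(layout)
  structure(
    list(layout = layout, colors = colors, pies = pies, fraction = fraction,
         shade_sz = shade_sz, width = width, height = height),
    class = "render_options"
  )
}

trait_palette <- function() {
  c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
    "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
    "#aec7e8", "#ffbb78", "#98df8a", "#ff9896", "#c5b0d5",
    "#c49c94", "#f7b6d2", "#c7c7c7", "#dbdb8d", "#9edae5")
}

state_colors <- function(states, colors = character()) {
  states <- sort(unique(states))
  pal <- trait_palette()
  out <- stats::setNames(pal[((seq_along(states) - 1L) %% length(pal)) + 1L], states)
  hit <- intersect(names(colors), states)
  out[hit] <- colors[hit]
  out
}

svg_el <- function(tag, ..., text = NULL) {
  attrs <- c(...)
  a <- if (length(attrs)) {
    paste0(" ", paste(sprintf('%s="%s"', names(attrs), attrs), collapse = " "))
  } else ""
  if (is.null(text)) sprintf("<%s%s/>", tag, a)
  else sprintf("<%s%s>%s</%s>", tag, a, xml_escape(text), tag)
}

svg_document <- function(body, width, height) {
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
      width, height, width, height
    ),
    body,
    "</svg>"
  ), collapse = "\n")
}

# node coordinates for all three layouts; x from root-to-node path lengths
# (unit lengths when absent), tips evenly spaced in display order
layout_coords <- function(tree, layout, width, height, margin = 40) {
  if (is.null(tree$edge.length)) {
    tree2 <- tree
    tree2$edge.length <- rep(1, nrow(tree$edge))
    dep <- node_depths(tree2)
  } else {
    dep <- node_depths(tree)
  }
  nn <- n_all_nodes(tree)
  ntip <- ape::Ntip(tree)
  ypos <- numeric(nn)
  ch <- children_list(tree)
  ord <- preorder_nodes(tree)
  tip_rank <- 0
  for (v in ord) if (v <= ntip) { tip_rank <- tip_rank + 1; ypos[v] <- tip_rank }
  for (v in rev(ord)) if (length(ch[[v]])) ypos[v] <- mean(ypos[ch[[v]]])
  xmax <- max(dep, 1e-12)
  if (layout == "radial") {
    ang <- 2 * pi * (ypos - 1) / max(ntip, 2)
    rad <- dep / xmax * (min(width, height) / 2 - margin)
    cx <- width / 2; cy <- height / 2
    tibble(node = seq_len(nn),
           x = cx + rad * cos(ang), y = cy + rad * sin(ang),
           angle = ang, depth = dep)
  } else {
    usable_w <- width - 2 * margin - 120 # room for tip labels
    tibble(node = seq_len(nn),
           x = margin + dep / xmax * usable_w,
           y = margin + (ypos - 1) / max(ntip - 1, 1) * (height - 2 * margin),
           angle = 0, depth = dep)
  }
}

pie_path <- function(cx, cy, r, f0, f1, fill) {
  a0 <- 2 * pi * f0 - pi / 2
  a1 <- 2 * pi * f1 - pi / 2
  large <- if ((f1 - f0) > 0.5) 1 else 0
  d <- sprintf(
    "M %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
    fmt_num(cx), fmt_num(cy),
    fmt_num(cx + r * cos(a0)), fmt_num(cy + r * sin(a0)),
    fmt_num(r), fmt_num(r), large,
    fmt_num(cx + r * cos(a1)), fmt_num(cy + r * sin(a1))
  )
  svg_el("path", d = d, fill = fill, stroke = "#333333", `stroke-width` = "0.5")
}

legend_elems <- function(cols, x, y) {
  out <- character(0)
  yy <- y
  for (s in names(cols)) {
    out <- c(out,
      svg_el("rect", x = fmt_num(x), y = fmt_num(yy - 8), width = "10",
             height = "10", fill = cols[[s]], class = "legend"),
      svg_el("text", x = fmt_num(x + 14), y = fmt_num(yy),
             `font-size` = "10", `font-family` = "sans-serif", text = s))
    yy <- yy + 16
  }
  out
}

#' Render an annotated tree as SVG
#'
#' Branches and nodes are colored by state where all supplied
#' reconstructions agree; where they disagree, one small bubble per method
#' is drawn in root-to-tip reading order. Posterior pie charts can be drawn
#' for ambiguous nodes, and node backgrounds can be shaded by the
#' descendant-size score.
#'
#' @param tree A rooted `phylo` tree.
#' @param reconstructions A single reconstruction or a named list of them
#'   (anything [as_node_states()] accepts), each covering every node.
#' @param options A [render_options] object.
#' @param posteriors Optional [marginal_posteriors] used for pie charts.
#' @param file Optional output path.
#' @return The SVG document as a single string (invisibly when written).
#' @export
render_tree <- function(tree, reconstructions, options = render_options(),
                        posteriors = NULL, file = NULL) {
  assert_phylo(tree)
  if (!inherits(options, "render_options")) abort("`options` must come from render_options().")
  if (!is.list(reconstructions) || inherits(reconstructions, "parsimony_fit") ||
      inherits(reconstructions, "joint_fit") || is.data.frame(reconstructions) ||
      inherits(reconstructions, "marginal_posteriors")) {
    reconstructions <- list(reconstruction = reconstructions)
  }
  stmat <- vapply(reconstructions, function(r) full_state_vec(tree, r),
                  character(n_all_nodes(tree)))
  cols <- state_colors(as.vector(stmat), options$colors)
  co <- layout_coords(tree, options$layout, options$width, options$height)
  par <- parent_vec(tree)
  nn <- n_all_nodes(tree)
  agree <- apply(stmat, 1, function(r) length(unique(r)) == 1L)
  body <- character(0)

  if (options$shade_sz) {
    sz <- size_criterion(tree, as_node_states(reconstructions[[1]]))
    mx <- max(sz$sz)
    for (v in seq_len(nn)) {
      body <- c(body, svg_el(
        "circle", cx = fmt_num(co$x[v]), cy = fmt_num(co$y[v]),
        r = fmt_num(6 + 6 * sz$sz[v] / mx), fill = "#000000",
        `fill-opacity` = fmt_num(0.08 + 0.25 * sz$sz[v] / mx), class = "sz"
      ))
    }
  }

  for (v in seq_len(nn)) {
    p <- par[v]
    if (p == 0L) next
    col <- if (agree[v]) cols[[stmat[v, 1]]] else "#555555"
    if (options$layout == "rectangular") {
      d <- sprintf("M %s %s V %s H %s",
                   fmt_num(co$x[p]), fmt_num(co$y[p]),
                   fmt_num(co$y[v]), fmt_num(co$x[v]))
      body <- c(body, svg_el("path", d = d, fill = "none", stroke = col,
                             `stroke-width` = "1.5", class = "edge"))
    } else {
      body <- c(body, svg_el("line",
        x1 = fmt_num(co$x[p]), y1 = fmt_num(co$y[p]),
        x2 = fmt_num(co$x[v]), y2 = fmt_num(co$y[v]),
        stroke = col, `stroke-width` = "1.5", class = "edge"))
    }
  }

  amb <- NULL
  if (options$pies && !is.null(posteriors)) {
    amb <- ambiguous_nodes(posteriors, options$fraction)
    post_by_node <- split(stats::setNames(posteriors$prob, posteriors$state),
                          posteriors$node)
  }

  for (v in seq_len(nn)) {
    if (!is.null(amb) && isTRUE(amb$ambiguous[amb$node == v])) {
      p <- post_by_node[[as.character(v)]]
      p <- sort(p[p > 1e-9], decreasing = TRUE)
      cum <- c(0, cumsum(p) / sum(p))
      for (i in seq_along(p)) {
        body <- c(body, pie_path(co$x[v], co$y[v], 8, cum[i], cum[i + 1],
                                 cols[[names(p)[i]]]))
      }
    } else if (agree[v]) {
      body <- c(body, svg_el("circle",
        cx = fmt_num(co$x[v]), cy = fmt_num(co$y[v]), r = "3",
        fill = cols[[stmat[v, 1]]], class = "node"))
    } else {
      # one bubble per method, root-to-tip reading order
      for (m in seq_len(ncol(stmat))) {
        body <- c(body, svg_el("circle",
          cx = fmt_num(co$x[v] + (m - 1) * 7), cy = fmt_num(co$y[v]),
          r = "3.2", fill = cols[[stmat[v, m]]],
          stroke = "#000000", `stroke-width` = "0.6",
          class = sprintf("bubble method-%d", m)))
      }
    }
  }

  for (v in seq_len(ape::Ntip(tree))) {
    body <- c(body, svg_el("text",
      x = fmt_num(co$x[v] + 6), y = fmt_num(co$y[v] + 3),
      `font-size` = "9", `font-family` = "sans-serif",
      text = tree$tip.label[v]))
  }

  body <- c(body, legend_elems(cols, options$width - 110, 24))
  doc <- svg_document(body, options$width, options$height)
  if (is.null(file)) return(doc)
  writeLines(doc, file)
  invisible(doc)
}

#' Render a transition map as SVG
#'
#' Map nodes are drawn as circles sized by collapse count and labeled
#' `state|count`; for type-1 maps the horizontal position is proportional
#' to the cumulative root-to-event distance. A compatibility marking (from
#' [map_compatibility()]) highlights shared nodes with an orange stroke.
#'
#' @param map A `transition_map`.
#' @param options A [render_options] object.
#' @param compat Optional tibble with columns `id`, `shared`.
#' @param file Optional output path.
#' @return The SVG document string (invisibly when written).
#' @export
render_map <- function(map, options = render_options(), compat = NULL,
                       file = NULL) {
  if (!inherits(map, "transition_map")) abort("`map` must be a transition_map.")
  nd <- map$nodes
  ch <- split(nd$id, factor(nd$parent, levels = c(0L, nd$id)))
  # tree-like coordinates over the map
  nlev <- integer(nrow(nd))
  for (v in nd$id) {
    p <- nd$parent[v]
    nlev[v] <- if (p == 0L) 0L else nlev[p] + 1L
  }
  xval <- if (map$type == 1L) nd$dist else as.numeric(nlev)
  xmax <- max(xval, 1e-12)
  leaves <- nd$id[!nd$id %in% nd$parent]
  ypos <- numeric(nrow(nd))
  rank <- 0
  assign_y <- function(v) {
    kids <- ch[[as.character(v)]]
    if (!length(kids)) {
      rank <<- rank + 1
      ypos[v] <<- rank
    } else {
      for (k in kids) assign_y(k)
      ypos[v] <<- mean(ypos[kids])
    }
  }
  assign_y(nd$id[nd$parent == 0L])
  w <- options$width; h <- options$height; margin <- 40
  if (options$layout == "radial") {
    ang <- 2 * pi * (ypos - 1) / max(length(leaves), 2)
    rad <- xval / xmax * (min(w, h) / 2 - margin)
    x <- w / 2 + rad * cos(ang); y <- h / 2 + rad * sin(ang)
  } else {
    x <- margin + xval / xmax * (w - 2 * margin - 120)
    y <- margin + (ypos - 1) / max(length(leaves) - 1, 1) * (h - 2 * margin)
  }
  cols <- state_colors(nd$state, options$colors)
  shared <- rep(FALSE, nrow(nd))
  if (!is.null(compat)) shared[match(compat$id, nd$id)] <- compat$shared
  body <- character(0)
  for (v in nd$id) {
    p <- nd$parent[v]
    if (p == 0L) next
    body <- c(body, svg_el("line",
      x1 = fmt_num(x[p]), y1 = fmt_num(y[p]),
      x2 = fmt_num(x[v]), y2 = fmt_num(y[v]),
      stroke = "#888888", `stroke-width` = "1", class = "edge"))
  }
  for (v in nd$id) {
    r <- 5 + 3 * sqrt(nd$count[v])
    body <- c(body, svg_el("circle",
      cx = fmt_num(x[v]), cy = fmt_num(y[v]), r = fmt_num(r),
      fill = cols[[nd$state[v]]],
      stroke = if (shared[v]) "#ff8c00" else "#333333",
      `stroke-width` = if (shared[v]) "3" else "1",
      class = "map-node"))
    body <- c(body, svg_el("text",
      x = fmt_num(x[v] + r + 3), y = fmt_num(y[v] + 3),
      `font-size` = "10", `font-family` = "sans-serif",
      text = sprintf("%s|%d", nd$state[v], nd$count[v])))
  }
  body <- c(body, legend_elems(cols, w - 110, 24))
  doc <- svg_document(body, w, h)
  if (is.null(file)) return(doc)
  writeLines(doc, file)
  invisible(doc)
}
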