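# BEAST-style annotated NEXUS import.
#
# ape::read.nexus discards the [&trait=...] node comments that carry the
# ancestral annotations, so the tree statement is parsed here with a small
# comment-aware Newick reader. Supported comment dialect, per node:
#   [&loc=X]  [&loc="two words"]  [&loc.set={"A","B"},loc.set.prob={0.8,0.2}]

#' Import a BEAST-style annotated NEXUS tree
#'
#' Reads the first tree of the TREES block (honouring a `translate` table)
#' together with its per-node bracket comments, and extracts one discrete
#' trait as a per-node state assignment. When the comment carries a
#' `<trait>.set` / `<trait>.set.prob` pair instead of a single value, the
#' majority (highest-probability) state is used, with lexicographic
#' tie-breaking, and the full distribution is returned as well.
#'
#' @param file Path to a NEXUS file, or the NEXUS text itself.
#' @param trait Name of the trait key to extract from the node comments.
#' @return A list with elements `tree` (a `phylo`), `states` (a tibble
#'   `node`, `state` covering every node that carries the trait) and
#'   `distributions` (a long tibble `node`, `state`, `prob`, or `NULL` when
#'   no `.set` annotations are present).
#' @export
import_nexus_annotated <- function(file, trait) {
  txt <- if (grepl("#NEXUS", file, ignore.case = TRUE) || grepl("\n", file)) {
    file
  } else {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    abort("Not a NEXUS file (missing #NEXUS header).")
  }
  if (!grepl("begin\\s+trees", txt, ignore.case = TRUE)) {
    abort("NEXUS file has no TREES block.")
  }
  translate <- parse_translate_block(txt)
  stmt <- extract_tree_statement(txt)
  parsed <- parse_newick_with_comments(stmt)
  tree <- parsed$tree
  if (length(translate)) {
    hit <- tree$tip.label %in% names(translate)
    tree$tip.label[hit] <- unname(translate[tree$tip.label[hit]])
  }
  ann <- extract_trait_annotations(parsed$comments, trait, tree)
  list(tree = tree, states = ann$states, distributions = ann$distributions)
}

parse_translate_block <- function(txt) {
  m <- regexpr("\\btranslate\\b", txt, ignore.case = TRUE)
  if (m < 0) return(character())
  rest <- substr(txt, m + attr(m, "match.length"), nchar(txt))
  end <- regexpr(";", rest, fixed = TRUE)
  if (end < 0) abort("Malformed translate table: missing ';'.")
  body <- substr(rest, 1, end - 1)
  entries <- strsplit(body, ",")[[1]]
  out <- character()
  for (e in entries) {
    e <- trimws(e)
    if (!nzchar(e)) next
    mm <- regmatches(e, regexec("^(\\S+)\\s+(.*)$", e))[[1]]
    if (length(mm) != 3) abort(sprintf("Malformed translate entry: '%s'", e))
    lab <- trimws(mm[3])
    lab <- gsub("^'(.*)'$", "\\1", lab)
    out[mm[2]] <- lab
  }
  out
}

extract_tree_statement <- function(txt) {
  m <- regexpr("\\btree\\s+\\S+\\s*=", txt, ignore.case = TRUE)
  if (m < 0) abort("No tree statement found in TREES block.")
  i <- m + attr(m, "match.length")
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  j <- i
  while (j <= length(chars)) {
    ch <- chars[j]
    if (ch == "'" && depth == 0L) in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      if (ch == ";" && depth == 0L) break
    }
    j <- j + 1L
  }
  if (j > length(chars)) abort("Unterminated tree statement (no ';').")
  stmt <- paste(chars[i:j], collapse = "")
  # drop the rooting comment [&R]/[&U] that precedes the newick
  stmt <- sub("^\\s*\\[&[RU]\\]\\s*", "", trimws(stmt))
  stmt
}

# Parse one newick statement keeping per-node bracket comments.
# Returns list(tree = phylo, comments = chr vector indexed by ape node id).
parse_newick_with_comments <- function(stmt) {
  chars <- strsplit(stmt, "", fixed = TRUE)[[1]]
  parent <- integer(0)
  label <- character(0)
  brlen <- numeric(0)
  comment <- character(0)
  kids <- list()

  new_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- ""
    brlen[length(brlen) + 1L] <<- NA_real_
    comment[length(comment) + 1L] <<- ""
    kids[[length(parent)]] <<- integer(0)
    id <- length(parent)
    if (p > 0L) kids[[p]] <<- c(kids[[p]], id)
    id
  }

  i <- 1L
  n <- length(chars)
  stack <- integer(0)
  cur <- 0L

  read_quoted <- function() {
    j <- i + 1L
    out <- character(0)
    while (j <= n) {
      if (chars[j] == "'") {
        if (j + 1L <= n && chars[j + 1L] == "'") { out <- c(out, "'"); j <- j + 2L; next }
        break
      }
      out <- c(out, chars[j]); j <- j + 1L
    }
    if (j > n) abort("Unterminated quoted label.")
    i <<- j + 1L
    paste(out, collapse = "")
  }
  read_bare <- function() {
    j <- i
    while (j <= n && !chars[j] %in% c("(", ")", ",", ":", ";", "[", "]")) j <- j + 1L
    out <- paste(chars[i:(j - 1L)], collapse = "")
    i <<- j
    trimws(out)
  }
  read_bracket <- function() {
    depth <- 0L
    j <- i
    while (j <= n) {
      if (chars[j] == "[") depth <- depth + 1L
      if (chars[j] == "]") { depth <- depth - 1L; if (depth == 0L) break }
      j <- j + 1L
    }
    if (j > n) abort("Unterminated '[' comment.")
    out <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
    i <<- j + 1L
    out
  }
  # comments and :length following a node; the first comment belongs to the
  # node itself (BEAST puts branch-level comments after the colon)
  read_node_suffix <- function(id) {
    repeat {
      if (i > n) break
      ch2 <- chars[i]
      if (ch2 == "[") {
        cm <- read_bracket()
        if (!nzchar(comment[id])) comment[id] <<- cm
      } else if (ch2 == ":") {
        i <<- i + 1L
        while (i <= n && chars[i] == "[") read_bracket()
        num <- read_bare()
        val <- suppressWarnings(as.numeric(num))
        if (is.na(val)) abort(sprintf("Malformed branch length '%s'.", num))
        brlen[id] <<- val
      } else {
        break
      }
    }
    id
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "(") {
      id <- new_node(if (length(stack)) stack[length(stack)] else 0L)
      stack <- c(stack, id)
      i <- i + 1L
    } else if (ch == ")") {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
      # optional internal label
      if (i <= n && !chars[i] %in% c("(", ")", ",", ":", ";", "[")) {
        label[cur] <- if (chars[i] == "'") read_quoted() else read_bare()
      }
      cur <- read_node_suffix(cur)
    } else if (ch == ",") {
      i <- i + 1L
    } else if (ch == ";") {
      break
    } else {
      id <- new_node(if (length(stack)) stack[length(stack)] else 0L)
      label[id] <- if (ch == "'") read_quoted() else read_bare()
      cur <- read_node_suffix(id)
    }
  }

  tips_mask <- lengths(kids) == 0L
  root_my <- which(parent == 0L)
  if (length(root_my) != 1L) abort("Malformed tree statement: no unique root.")
  ntip <- sum(tips_mask)
  if (ntip < 2L) abort("Tree statement has fewer than two tips.")

  # map my preorder-creation ids to ape ids
  ids <- integer(length(parent))
  ids[which(tips_mask)] <- seq_len(ntip)
  internal_my <- c(root_my, setdiff(which(!tips_mask), root_my))
  ids[internal_my] <- ntip + seq_along(internal_my)

  edge <- matrix(0L, nrow = length(parent) - 1L, ncol = 2)
  k <- 0L
  stack2 <- root_my
  while (length(stack2)) {
    v <- stack2[[length(stack2)]]
    stack2 <- stack2[-length(stack2)]
    for (c_my in kids[[v]]) {
      k <- k + 1L
      edge[k, ] <- c(ids[v], ids[c_my])
    }
    if (length(kids[[v]])) stack2 <- c(stack2, rev(kids[[v]]))
  }
  # rows were appended in DFS order but children-first blocks need preorder;
  # re-emit in preorder of parents
  tree <- list(
    edge = edge,
    tip.label = label[tips_mask][order(ids[tips_mask])],
    Nnode = length(internal_my)
  )
  el <- brlen[order(ids)][edge[, 2]]
  if (any(!is.na(el))) {
    el[is.na(el)] <- 0
    tree$edge.length <- el
  }
  nl <- label[internal_my]
  if (any(nzchar(nl))) tree$node.label <- nl
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  comments_by_id <- comment[order(ids)]
  list(tree = tree, comments = comments_by_id)
}

extract_trait_annotations <- function(comments, trait, tree) {
  nn <- n_all_nodes(tree)
  states <- rep(NA_character_, nn)
  dist_rows <- list()
  for (v in seq_len(nn)) {
    cm <- comments[v]
    if (!nzchar(cm)) next
    kv <- parse_comment_fields(cm)
    if (!is.null(kv[[trait]])) {
      states[v] <- kv[[trait]]
    } else if (!is.null(kv[[paste0(trait, ".set")]])) {
      set <- parse_brace_vector(kv[[paste0(trait, ".set")]])
      prb <- kv[[paste0(trait, ".set.prob")]]
      prb <- if (is.null(prb)) rep(1 / length(set), length(set)) else
        as.numeric(parse_brace_vector(prb))
      if (length(prb) != length(set) || anyNA(prb)) {
        abort(sprintf("Malformed %s.set.prob on node %d.", trait, v))
      }
      o <- order(-prb, set)
      states[v] <- set[o[1]]
      dist_rows[[length(dist_rows) + 1L]] <-
        tibble(node = v, state = set, prob = prb)
    }
  }
  internal <- (ape::Ntip(tree) + 1L):nn
  missing_int <- internal[is.na(states[internal])]
  if (length(missing_int)) {
    abort(sprintf(
      "Trait '%s' absent on internal node(s): %s", trait,
      paste(utils::head(missing_int, 10), collapse = ", ")
    ))
  }
  keep <- which(!is.na(states))
  list(
    states = node_states(keep, states[keep]),
    distributions = if (length(dist_rows)) bind_rows(dist_rows) else NULL
  )
}

# "&loc=\"X\",rate=0.3,loc.set={...}" -> named list of raw value strings
parse_comment_fields <- function(cm) {
  cm <- sub("^&", "", cm)
  chars <- strsplit(cm, "", fixed = TRUE)[[1]]
  fields <- character(0)
  depth <- 0L
  in_q <- FALSE
  buf <- character(0)
  for (ch in chars) {
    if (ch == "\"") in_q <- !in_q
    if (!in_q) {
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
      if (ch == "," && depth == 0L) {
        fields <- c(fields, paste(buf, collapse = ""))
        buf <- character(0)
        next
      }
    }
    buf <- c(buf, ch)
  }
  if (length(buf)) fields <- c(fields, paste(buf, collapse = ""))
  out <- list()
  for (f in fields) {
    eq <- regexpr("=", f, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(f, 1, eq - 1))
    val <- trimws(substr(f, eq + 1, nchar(f)))
    val <- gsub("^\"(.*)\"$", "\\1", val)
    out[[key]] <- val
  }
  out
}

parse_brace_vector <- function(val) {
  val <- gsub("^\\{|\\}$", "", val)
  parts <- strsplit(val, ",")[[1]]
  parts <- trimws(parts)
  gsub("^\"(.*)\"$", "\\1", parts)
}
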