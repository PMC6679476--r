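#' Parse a Newick tree
#'
#' Reads a single rooted Newick statement into an [ape::phylo] object. Child
#' order is preserved as written, branch lengths and internal labels are kept
#' when present, and quoted labels are taken verbatim (underscores are *not*
#' converted to spaces by this package's readers and writers, so a
#' parse/write round trip is lossless).
#'
#' Node ids used throughout the package follow the `ape` convention: tips are
#' numbered `1..Ntip` in `tip.label` order, the root is `Ntip + 1` and the
#' remaining internal nodes follow.
#'
#' @param text A Newick string terminated by `;`, or the path of a file
#'   containing one.
#' @return A `phylo` tree.
#' @examples
#' tr <- parse_newick("((A:1,B:1):0.5,C:2);")
#' node_table(tr)
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    abort("`text` must be a single character string.")
  }
  if (!grepl(";", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) abort("Empty Newick input.")
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort("Failed to parse Newick input.")
  if (inherits(tree, "multiPhylo")) {
    abort("Input contains more than one Newick statement; expected exactly one.")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    abort(sprintf("Duplicate leaf label(s): %s", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(tree$tip.label))) abort("Empty leaf label in Newick input.")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("Negative branch length in Newick input.")
  }
  kids <- sum(tree$edge[, 1] == root_node(tree))
  if (kids == 3L) {
    warn(
      "Root has three children: input may be an unrooted tree; treating it as rooted at the outermost node.",
      class = "traitmaps_unrooted"
    )
  }
  tree
}

# cheap structural checks so malformed input fails with a position, not
# with whatever ape improvises
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(sprintf("Unbalanced ')' at position %d.", i))
    }
  }
  if (depth != 0L) abort(sprintf("Unbalanced parentheses: %d '(' left open.", depth))
  if (!grepl(";\\s*$", text)) abort("Newick statement must end with ';'.")
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  assert_phylo(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Per-node summary table of a tree
#'
#' @param tree A `phylo` tree.
#' @return A tibble with one row per node: `node`, `parent` (0 for the root),
#'   `label`, `branch_length` (NA for the root or when absent), `depth`
#'   (root-to-node path length; absent lengths count 0), `is_tip`.
#' @export
node_table <- function(tree) {
  assert_phylo(tree)
  n <- n_all_nodes(tree)
  tibble(
    node = seq_len(n),
    parent = parent_vec(tree),
    label = node_labels(tree),
    branch_length = edge_length_vec(tree),
    depth = node_depths(tree),
    is_tip = seq_len(n) <= ape::Ntip(tree)
  )
}

#' Construct a discrete-character tip annotation set
#'
#' @param taxon Character vector of taxon (tip) labels.
#' @param state Character vector of state labels; `NA` marks a taxon with
#'   missing annotation (treated as fully ambiguous by the reconstructions).
#' @param name Name of the character (e.g. `"country"`).
#' @param alphabet Optional state alphabet; defaults to the sorted set of
#'   observed states. Must cover every non-missing state.
#' @return A tibble of class `character_data` with columns `taxon`, `state`
#'   and attributes `char_name` and `alphabet`.
#' @export
character_data <- function(taxon, state, name = "trait", alphabet = NULL) {
  taxon <- as.character(taxon)
  state <- as.character(state)
  if (length(taxon) != length(state)) abort("`taxon` and `state` lengths differ.")
  dup <- unique(taxon[duplicated(taxon)])
  if (length(dup)) abort(sprintf("Duplicate taxon row(s): %s", paste(dup, collapse = ", ")))
  observed <- sort(unique(state[!is.na(state)]))
  if (is.null(alphabet)) alphabet <- observed
  alphabet <- sort(unique(as.character(alphabet)))
  extra <- setdiff(observed, alphabet)
  if (length(extra)) {
    abort(sprintf("State(s) outside the alphabet: %s", paste(extra, collapse = ", ")))
  }
  if (!length(alphabet)) abort("Alphabet is empty: no states observed or supplied.")
  out <- tibble(taxon = taxon, state = state)
  attr(out, "char_name") <- name
  attr(out, "alphabet") <- alphabet
  class(out) <- c("character_data", class(out))
  out
}

#' @export
print.character_data <- function(x, ...) {
  cat(sprintf(
    "<character_data> '%s': %d taxa (%d missing), alphabet {%s}\n",
    attr(x, "char_name"), nrow(x), sum(is.na(x$state)),
    paste(attr(x, "alphabet"), collapse = ", ")
  ))
  NextMethod()
}

#' State alphabet of an annotation set
#' @param data A `character_data` object.
#' @return Character vector of state labels.
#' @export
state_alphabet <- function(data) attr(data, "alphabet")

#' Read tip annotations from CSV
#'
#' The file must have a header row; the taxon identifier column is the first
#' column unless named via `taxon_col`, and the character column defaults to
#' the first remaining column. Empty cells become missing annotations.
#'
#' @param file Path to a CSV file, or a literal CSV string.
#' @param character Name of the character column to use (default: first
#'   non-taxon column).
#' @param taxon_col Name of the taxon column (default: first column).
#' @param alphabet Optional fixed state alphabet.
#' @return A [character_data] tibble.
#' @export
read_annotations_csv <- function(file, character = NULL, taxon_col = NULL,
                                 alphabet = NULL) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) abort("Annotation CSV needs a taxon column plus at least one character column.")
  if (is.null(taxon_col)) taxon_col <- names(df)[1]
  if (!taxon_col %in% names(df)) abort(sprintf("Taxon column '%s' not found.", taxon_col))
  if (is.null(character)) character <- setdiff(names(df), taxon_col)[1]
  if (!character %in% names(df)) abort(sprintf("Character column '%s' not found.", character))
  st <- df[[character]]
  st[!is.na(st) & !nzchar(trimws(st))] <- NA_character_
  character_data(df[[taxon_col]], st, name = character, alphabet = alphabet)
}

#' Bind tip annotations to a tree
#'
#' @param tree A `phylo` tree.
#' @param data A [character_data] object.
#' @return Character vector of length `Ntip(tree)` of states (NA = missing),
#'   indexed by tip id.
#' @export
tip_states <- function(tree, data) {
  assert_phylo(tree)
  unknown <- setdiff(data$taxon, tree$tip.label)
  if (length(unknown)) {
    abort(sprintf(
      "Annotated taxa absent from the tree: %s",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  st <- rep(NA_character_, ape::Ntip(tree))
  idx <- match(data$taxon, tree$tip.label)
  st[idx] <- data$state
  st
}

#' Per-node state assignments
#'
#' Light validated container used for reconstructed or imported ancestral
#' annotations: one state per node id.
#'
#' @param node Integer node ids (ape convention).
#' @param state Character states.
#' @param tree Optional tree to validate ids against.
#' @return A tibble with columns `node`, `state`.
#' @export
node_states <- function(node, state, tree = NULL) {
  node <- as.integer(node)
  state <- as.character(state)
  if (length(node) != length(state)) abort("`node` and `state` lengths differ.")
  if (anyDuplicated(node)) abort("Duplicate node ids in state assignment.")
  if (!is.null(tree)) {
    assert_phylo(tree)
    bad <- setdiff(node, seq_len(n_all_nodes(tree)))
    if (length(bad)) abort(sprintf("Node id(s) not in tree: %s", paste(bad, collapse = ", ")))
  }
  arrange(tibble(node = node, state = state), node)
}

# ---- tree edits -----------------------------------------------------------

#' Basic tree edits: reroot, ladderize, swap
#'
#' `reroot_tree()` reroots at a node (tip or internal), preserving the
#' pairwise path lengths between leaves; rerooting at the current root is a
#' flagged no-op. `ladderize_tree()` sorts children by subtree size and is
#' idempotent. `swap_children()` reverses the child order of one node and is
#' an involution. None of the edits changes the leaf label multiset.
#'
#' @param tree A `phylo` tree.
#' @param node Target node id.
#' @param right Ladderize direction, as in [ape::ladderize].
#' @return The edited `phylo` tree. A no-op reroot carries
#'   `attr(, "reroot_noop") = TRUE`.
#' @export
reroot_tree <- function(tree, node) {
  assert_phylo(tree)
  if (node == root_node(tree)) {
    warn("Node is already the root; returning the tree unchanged.",
         class = "traitmaps_reroot_noop")
    attr(tree, "reroot_noop") <- TRUE
    return(tree)
  }
  if (is_leaf(tree, node)) {
    out <- ape::root(tree, outgroup = node, resolve.root = TRUE)
  } else {
    out <- ape::root(tree, node = node, resolve.root = TRUE)
  }
  out
}

#' @rdname reroot_tree
#' @export
ladderize_tree <- function(tree, right = TRUE) {
  assert_phylo(tree)
  ape::ladderize(tree, right = right)
}

#' @rdname reroot_tree
#' @export
swap_children <- function(tree, node) {
  assert_phylo(tree)
  if (node > n_all_nodes(tree) || node <= ape::Ntip(tree)) {
    abort("`node` must be an internal node id.")
  }
  rows <- which(tree$edge[, 1] == node)
  if (length(rows) < 2L) return(tree)
  perm <- seq_len(nrow(tree$edge))
  perm[rows] <- rev(rows)
  tree$edge <- tree$edge[perm, , drop = FALSE]
  if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[perm]
  # re-read to restore canonical cladewise numbering for the new child order
  parse_quiet(ape::write.tree(tree))
}

parse_quiet <- function(txt) {
  withCallingHandlers(
    parse_newick(txt),
    traitmaps_unrooted = function(w) invokeRestart("muffleWarning")
  )
}

#' @rdname reroot_tree
#' @param action One of `"reroot"`, `"ladderize"`, `"swap"`.
#' @export
edit_tree <- function(tree, action = c("reroot", "ladderize", "swap"),
                      node = NULL, right = TRUE) {
  action <- match.arg(action)
  switch(action,
    reroot = reroot_tree(tree, node),
    ladderize = ladderize_tree(tree, right = right),
    swap = swap_children(tree, node)
  )
}
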