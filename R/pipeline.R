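# End-to-end orchestration: load -> reconstruct -> transitions -> compare
# -> report. The thin command-line wrapper in exec/traitmaps drives this.

#' Run the full analysis pipeline
#'
#' Loads a tree with tip annotations (Newick + CSV) or an annotated NEXUS
#' tree, runs the requested reconstruction methods, extracts transitions,
#' builds the three transition-map levels and both matrices per method,
#' compares methods node-wise, and writes CSV / Newick / SVG artifacts plus
#' a JSON run summary into `out_dir`.
#'
#' @param tree Path to a Newick file, or a `phylo` tree (ignored when
#'   `nexus` is given).
#' @param annotations Path to an annotation CSV, or a [character_data].
#' @param character Character column to use from the CSV.
#' @param nexus Path to (or text of) a BEAST-style annotated NEXUS file.
#' @param trait Trait name for the NEXUS import.
#' @param methods Subset of `"map"`, `"joint"`, `"acctran"`, `"deltran"`,
#'   plus `"imported"` when a NEXUS annotation is loaded.
#' @param priors `"observed"` (smoothed leaf frequencies), `"uniform"`, or
#'   a named numeric vector.
#' @param sigma `"auto"` (fit by ML) or a fixed positive number.
#' @param fraction Ambiguity fraction for the pie-chart filter.
#' @param out_dir Output directory (created if missing).
#' @param layout SVG layout.
#' @param draw Write SVG files.
#' @param seed Optional seed (stored in the summary; the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the reconstructions, maps, comparison and
#'   the summary (also written as `summary.json`).
#' @export
run_pipeline <- function(tree = NULL, annotations = NULL, character = NULL,
                         nexus = NULL, trait = NULL,
                         methods = c("map", "joint", "acctran", "deltran"),
                         priors = "observed", sigma = "auto", fraction = 0.4,
                         out_dir = ".", layout = "rectangular", draw = TRUE,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  imported <- NULL

  if (!is.null(nexus)) {
    if (is.null(trait)) abort("stage load: `trait` is required with `nexus`.")
    imp <- stage("load", import_nexus_annotated(nexus, trait))
    phy <- imp$tree
    imported <- imp$states
    tipst <- imp$states |> filter(.data$node <= ape::Ntip(phy))
    data <- character_data(phy$tip.label[tipst$node], tipst$state, name = trait)
    methods <- union(methods, "imported")
  } else {
    if (is.null(tree) || is.null(annotations)) {
      abort("stage load: need `tree` + `annotations`, or `nexus` + `trait`.")
    }
    phy <- if (inherits(tree, "phylo")) tree else stage("load", parse_newick(tree))
    data <- if (inherits(annotations, "character_data")) annotations else
      stage("load", read_annotations_csv(annotations, character = character))
  }

  needs_ml <- any(c("map", "joint") %in% methods)
  model <- NULL
  post <- NULL
  recs <- list()
  if (needs_ml) {
    pr <- if (identical(priors, "observed")) estimate_priors(data)
      else if (identical(priors, "uniform")) {
        a <- state_alphabet(data)
        stats::setNames(rep(1 / length(a), length(a)), a)
      } else priors
    phy_ml <- ensure_branch_lengths(phy)
    model <- if (identical(sigma, "auto")) {
      stage("fit", fit_scaling_factor(phy_ml, data, priors = pr))
    } else {
      m <- f81_model(pr, sigma = as.numeric(sigma))
      m$loglik <- tree_log_likelihood(phy_ml, data, m)
      m
    }
    if ("map" %in% methods) {
      post <- stage("reconstruct", marginal_posteriors(phy_ml, data, model))
      recs$map <- as_node_states(post)
      readr::write_csv(
        tidyr::pivot_wider(post, names_from = "state", values_from = "prob"),
        file.path(out_dir, "posteriors_map.csv"))
    }
    if ("joint" %in% methods) recs$joint <- as_node_states(
      stage("reconstruct", joint_reconstruction(phy_ml, data, model)))
  }
  if ("acctran" %in% methods) recs$acctran <- as_node_states(
    stage("reconstruct", acctran(phy, data)))
  if ("deltran" %in% methods) recs$deltran <- as_node_states(
    stage("reconstruct", deltran(phy, data)))
  if ("imported" %in% methods && !is.null(imported)) recs$imported <- imported
  if (!length(recs)) abort("stage reconstruct: no valid method selected.")

  labels <- node_labels(phy)
  n_events <- integer(0)
  maps <- list()
  for (m in names(recs)) {
    st <- recs[[m]]
    readr::write_csv(mutate(st, label = labels[.data$node]),
                     file.path(out_dir, sprintf("states_%s.csv", m)))
    ev <- stage("transitions", extract_transitions(phy, st))
    n_events[m] <- nrow(ev)
    readr::write_csv(as_tibble(ev), file.path(out_dir, sprintf("events_%s.csv", m)))
    m1 <- build_map_type1(phy, st)
    m2 <- collapse_type2(m1)
    m3 <- collapse_type3(m2)
    maps[[m]] <- list(type1 = m1, type2 = m2, type3 = m3)
    for (ty in 1:3) {
      map_to_newick(maps[[m]][[ty]],
                    file.path(out_dir, sprintf("map_%s_type%d.nwk", m, ty)))
    }
    cm <- transition_count_matrix(ev, alphabet = state_alphabet(data))
    readr::write_csv(tidy.transition_matrix(cm),
                     file.path(out_dir, sprintf("matrix_counts_%s.csv", m)))
    pr_all <- if (!is.null(model)) {
      stats::setNames(model$pi, model$alphabet)
    } else {
      estimate_priors(data)
    }
    rm_ <- suppressWarnings(relative_rate_matrix(cm, pr_all))
    readr::write_csv(tidy.transition_matrix(rm_),
                     file.path(out_dir, sprintf("matrix_rates_%s.csv", m)))
    if (draw) {
      opts <- render_options(layout = layout, fraction = fraction)
      render_map(maps[[m]]$type2, opts,
                 file = file.path(out_dir, sprintf("map_%s_type2.svg", m)))
    }
  }

  comparison <- NULL
  if (length(recs) >= 2L) {
    comparison <- stage("compare", discrepant_nodes(recs, phy))
    readr::write_csv(comparison$table, file.path(out_dir, "comparison.csv"))
  }

  if (draw) {
    opts <- render_options(layout = layout, fraction = fraction,
                           pies = !is.null(post))
    stage("report", render_tree(phy, recs, opts, posteriors = post,
                                file = file.path(out_dir, "tree.svg")))
  }

  summary <- list(
    n_tips = ape::Ntip(phy),
    methods = names(recs),
    sigma = if (!is.null(model)) model$sigma else NULL,
    loglik = if (!is.null(model)) model$loglik else NULL,
    n_events = as.list(n_events),
    n_discrepant = if (!is.null(comparison)) comparison$n_discrepant else NULL,
    seed = seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tree = phy, data = data, model = model, posteriors = post,
                 reconstructions = recs, maps = maps, comparison = comparison,
                 summary = summary))
}

# tag failures with the pipeline stage they came from
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s: %s", name, conditionMessage(e)), parent = e)
  })
}

#' Write a simulated dataset to disk
#'
#' Convenience wrapper around [sim_yule_tree()] and [simulate_character()]:
#' writes `<prefix>.nwk` (tree), `<prefix>_tips.csv` (leaf annotations) and
#' `<prefix>_truth.csv` (true states of all nodes).
#'
#' @param n Number of tips.
#' @param n_states Alphabet size (states `s1..sK`, uniform priors).
#' @param sigma Branch-length scaling factor used for simulation.
#' @param seed Seed (required: outputs are part of reproducible runs).
#' @param prefix Output path prefix.
#' @return Invisibly, the list from [simulate_character()] plus the tree.
#' @export
simulate_dataset <- function(n, n_states = 3, sigma = 1, seed = 1,
                             prefix = "sim") {
  alphabet <- paste0("s", seq_len(n_states))
  pr <- stats::setNames(rep(1 / n_states, n_states), alphabet)
  tree <- sim_yule_tree(n, seed = seed)
  model <- f81_model(pr, sigma = sigma)
  sim <- simulate_character(tree, model, seed = seed + 1L)
  write_newick(tree, paste0(prefix, ".nwk"))
  readr::write_csv(tibble(taxon = sim$tips$taxon, state = sim$tips$state),
                   paste0(prefix, "_tips.csv"))
  readr::write_csv(sim$truth, paste0(prefix, "_truth.csv"))
  invisible(list(tree = tree, tips = sim$tips, truth = sim$truth,
                 model = model))
}
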