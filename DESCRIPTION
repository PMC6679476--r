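Package: traitmaps
Title: Ancestral Discrete Character States and Transition Map Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ancestral states of a discrete character on a rooted
    phylogeny by parsimony (ACCTRAN and DELTRAN resolutions) and by maximum
    likelihood under an F81-like substitution model with a globally fitted
    branch-length scaling factor (marginal posteriors with MAP states, and
    the jointly most likely reconstruction by dynamic programming).
    Summarizes the resulting evolutionary scenarios as transition maps of
    three collapse levels, transition count and relative-rate matrices,
    wildcard path queries, ambiguity filters and descendant-size scores,
    and compares reconstructions across methods. Reads Newick trees, CSV
    tip annotations and BEAST-style annotated NEXUS trees; writes CSV,
    Newick and SVG. Includes a seeded simulator (Yule trees, F81 character
    evolution) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
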