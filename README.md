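# traitmaps

Ancestral discrete character states on rooted phylogenies, and the
scenario summaries built from them.

Phylogenetic trees combined with a discrete extrinsic trait — geographic
origin, host, drug resistance, habitat — let researchers in phylogeography,
molecular epidemiology and ecology reconstruct how the trait changed from
the root to the tips. `traitmaps` is a headless toolkit for that workflow:
it infers ancestral states, extracts the *transitions* (top-down changes of
state between a node and its parent), and condenses them into compact,
queryable summaries.

## What it computes

**Reconstruction methods**

* *Parsimony* with Hartigan-style set computation (multifurcations are
  first-class) and both classic ambiguity resolutions: **ACCTRAN**
  (changes accelerated toward the root) and **DELTRAN** (changes delayed
  toward the tips). Both realize the minimum change count.
* *Maximum likelihood* under an **F81-like model**: the probability of
  ending in state *j* after a branch of length *t* is

  P(i→j | t) = π<sub>j</sub>(1 − e<sup>−μσt</sup>) + [i=j]·e<sup>−μσt</sup>,
  μ = 1 / (1 − Σ<sub>s</sub> π<sub>s</sub>²),

  with state priors π estimated from smoothed tip frequencies (or fixed by
  the user) and a single branch-length **scaling factor σ** fitted by
  maximum likelihood, so sequence-derived branch lengths are rescaled to
  the evolutionary rate of the analyzed character. From the fitted model
  the package computes **marginal posteriors** (and their per-node **MAP**
  states) by inside–outside tree traversals, and the **jointly most
  likely** full assignment by max-product dynamic programming.
* Imported reconstructions: BEAST-style annotated NEXUS trees
  (`[&trait=...]` or `trait.set`/`trait.set.prob` node comments) load as a
  further "method" for comparison.

**Scenario summaries**

* **Transition maps** of three collapse levels: type 1 keeps one map node
  per transition event (with cumulative root distances); type 2 merges
  identical sibling transitions, displaying the collapse count; type 3
  merges identical transitions that share the ancestral state anywhere in
  the type-2 map. Exportable as Newick (`state|count` labels) and SVG.
* **Transition matrices**: raw counts, and count-based relative rates
  (counts normalized by the total and divided by state priors).
* **Wildcard path queries**: `"GREECE * ALBANIA"` finds every root-to-leaf
  pathway whose compressed state sequence passes from GREECE to ALBANIA
  through any intermediaries.
* **Ambiguity filter** (states within a fraction of the MAP posterior) and
  the **Sz** descendant-size score (same-state leaves below a node).
* **Method comparison**: node-wise discrepancies between any set of
  reconstructions, and compatibility marking between transition maps.

Results are tibbles (with `tidy()` / `glance()` methods on fitted objects
and `autoplot()` for maps, matrices and posteriors); trees are standard
`ape::phylo` objects; rendering produces deterministic SVG.

## Worked example

The package ships a small fully annotated tree (`fig3_fixture()`, also as
plain files under `inst/extdata/`): a gray root with two gray leaves, two
red clades and two gold leaves, branch lengths 1.

```r
library(traitmaps)

fx <- fig3_fixture()
extract_transitions(fx$tree, fx$states)
#> # A tibble: 4 × 4
#>    node from  to    distance
#>   <int> <chr> <chr>    <dbl>
#> 1     9 gray  red          1
#> 2     4 red   gold         2
#> 3    10 gray  red          1
#> 4     7 gray  gold         1
```

Four transitions: gray→red twice, gray→gold once, red→gold once, each with
its root-to-node distance. Collapsing the type-1 map to type 2 merges the
two sibling gray→red events into one node with count 2:

```r
m2 <- collapse_type2(build_map_type1(fx$tree, fx$states))
tidy(m2)[, c("id", "parent", "from", "state", "count", "dist")]
#> # A tibble: 4 × 6
#>      id parent from  state count  dist
#>   <int>  <int> <chr> <chr> <int> <dbl>
#> 1     1      0 <NA>  gray      1     0
#> 2     2      1 gray  red       2     1
#> 3     3      1 gray  gold      1     1
#> 4     4      2 red   gold      1     2
map_to_newick(m2)
#> [1] "((gold|1)red|2,gold|1)gray|1;"
```

Counts and relative rates (counts normalized and divided by the
destination state's prior):

```r
ev <- extract_transitions(fx$tree, fx$states)
transition_count_matrix(ev)
#>       to
#> from   gold gray red
#>   gold    0    0   0
#>   gray    1    0   2
#>   red     1    0   0
round(relative_rate_matrix(transition_count_matrix(ev), estimate_priors(fx$tips)), 3)
#>       to
#> from    gold gray  red
#>   gold 0.000    0 0.00
#>   gray 0.833    0 1.25
#>   red  0.833    0 0.00
```

Parsimony on the tip states alone recovers the same four changes:

```r
acctran(fx$tree, fx$tips)
#> <parsimony_fit> ACCTRAN: score 4 over 10 nodes, alphabet {gold, gray, red}
```

And the ML machinery recovers a known scaling factor from simulated data
(σ = 2 used to simulate a 3-state character on a 200-leaf Yule tree):

```r
tr  <- sim_yule_tree(200, seed = 42)
sim <- simulate_character(tr, f81_model(c(east = .4, north = .35, west = .25),
                                        sigma = 2), seed = 43)
glance(fit_scaling_factor(tr, sim$tips))
#> # A tibble: 1 × 4
#>   n_states    mu sigma loglik
#>      <int> <dbl> <dbl>  <dbl>
#> 1        3  1.54  2.03  -202.
```

A thin command-line front end (`exec/traitmaps`) exposes the same steps as
subcommands (`simulate`, `reconstruct`, `transitions`, `matrix`, `query`,
`compare`, `draw`, `run`); `run_pipeline()` executes the whole chain and
writes CSV, Newick, SVG and a JSON summary.

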