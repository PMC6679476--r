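---
title: "Ancestral trait scenarios: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral trait scenarios: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitmaps)
```

`traitmaps` reconstructs the ancestral states of one discrete character on
a rooted phylogeny and condenses the resulting scenario — the top-down
sequence of state changes — into transition maps, matrices and path
queries. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## Data model

Trees are `ape::phylo` objects, and all node references use ape's
numbering: tips `1..N` in `tip.label` order, the root at `N + 1`, further
internal nodes after it. Multifurcations are supported everywhere. Tip
annotations are held in a `character_data` tibble (taxon, state) carrying
the character's name and its state alphabet; a tip absent from the table,
or with an empty cell, is *missing* and is treated as fully ambiguous —
every state is possible — by both reconstruction families. This is the
standard convention; nothing in the data can justify a more informative
choice.

## Parsimony: ACCTRAN and DELTRAN

The minimum-change machinery is a unit-cost Sankoff dynamic program: for
every node `v` and state `s`, `c[v, s]` is the minimum number of changes
in `v`'s subtree given `state(v) = s`. This handles polytomies natively
(the Hartigan generalization of the Fitch downpass falls out as the
argmin sets of `c`), and the parsimony score is `min_s c[root, s]`.

A single-state-per-node labeling is produced by a top-down traceback:
the root takes an argmin state, and a child `v` of a parent fixed at `p`
may take any state in `argmin_s (c[v, s] + [s != p])`. Every such choice
extends to a globally minimal labeling, so both resolutions are guaranteed
to realize the minimum change count — a property the test suite verifies
against brute-force enumeration. Where the argmin is not unique:

* **ACCTRAN** prefers a state *different* from the parent, placing changes
  as close to the root as admissible;
* **DELTRAN** prefers the parent's state, delaying changes toward the
  tips;
* remaining ties are broken lexicographically, so results are
  deterministic and independent of input order.

On the textbook four-tip case `(((A,B),C),D)` with states `1,0,1,0` this
yields the classic split: ACCTRAN infers one change on the deep edge plus
a reversal, DELTRAN two parallel tip-edge changes. Note that the two
resolutions can differ at a node whose *downpass* set is a singleton (the
deep node in that example has downpass set `{1}` yet DELTRAN assigns `0`);
the correct characterization is through the **MPR set** — the states a
node takes in at least one minimum-change labeling — which the package
computes by an additional outside pass and reports alongside the downpass
sets. The invariant "ACCTRAN and DELTRAN agree wherever the MPR set is a
singleton" is property-tested.

Branch lengths play no role in parsimony, by definition.

## The F81-like likelihood model

The substitution process is the one whose transition probability depends
only on the target state's stationary frequency and the elapsed time:

$$P(i \to j \mid t) \;=\; \pi_j\,(1 - e^{-\mu\sigma t}) \;+\;
  [i = j]\, e^{-\mu\sigma t},$$

with normalization rate $\mu = 1/(1 - \sum_s \pi_s^2)$ so that one unit of
scaled time corresponds to one expected substitution at stationarity, and
a single scaling factor $\sigma > 0$ applied to every branch. With equal
frequencies over four states this reduces exactly to Jukes–Cantor
($\mu = 4/3$), which the tests use as a closed-form oracle. The chain is
time-reversible, so the likelihood does not depend on root placement —
also property-tested. We adopt the $\mu$-normalized parameterization and
flag it here: with $\mu$ absorbed into $\sigma$ the likelihood surface is
identical up to a rescaling of $\sigma$, so nothing downstream depends on
the convention, but reported $\sigma$ values do.

**Priors** default to observed tip frequencies with add-one smoothing,
$\pi_s = (n_s + 1)/(n + K)$, which keeps every $\pi_s > 0$ as the model
requires even when a state appears only in imported ancestral annotations.
Uniform or user-fixed priors are available (`priors` arguments, CLI
`--priors`). Priors are estimated first and held fixed while $\sigma$ is
fitted; a joint fit would add `K - 1` dimensions for little benefit at the
tree sizes this package targets.

**Scaling factor.** Branch lengths typically come from sequence data and
are in substitutions/site; $\sigma$ (dimensionless) rescales them to the
character's rate. It is fitted by Brent search on $\log\sigma \in
[\log 10^{-3}, \log 10^3]$ with tolerance $10^{-6}$ in log space; the
likelihood is unimodal in $\sigma$ in practice, and the bounds prevent
runaway on uninformative data. With fewer than two observed states the
factor is unidentifiable and the fit returns $\sigma = 1$ with a warning;
a fit landing at a search bound is also flagged. Trees without branch
lengths get unit lengths (warned), so $\sigma$ absorbs the unit.
Rescaling all input lengths by a constant `c` rescales the fitted
$\sigma$ by `1/c` — verified as an invariance test.

**Numerics.** Felsenstein pruning renormalizes the per-node partial
likelihood vector and accumulates the log scaler, rather than working in
per-entry log space; this is the standard trick and is exact (the tests
compare against exhaustive summation to $10^{-10}$ in log likelihood on
small instances). Zero-length branches use the exact identity matrix — no
epsilon inflation — so data that conflict across a zero-length edge yield
a `-Inf` log-likelihood rather than an error or a silently smoothed
value. Marginal posteriors come from one bottom-up and one top-down pass
(inside × outside, renormalized per node); the joint reconstruction is
max-product dynamic programming with back-pointers in log space. Argmax
tie-breaks, in MAP states and in the joint traceback, are lexicographic
and flagged (`tie` column), again for determinism. MAP-of-marginals and
the joint assignment are different estimators and can disagree; the suite
constructs such a case and treats the disagreement as legitimate.

## Transitions and their summaries

A transition is read top-down: an edge `(u, v)` whose states differ
contributes one event, attributed to the child `v`, at distance equal to
the root-to-`v` path length (edges without stored lengths contribute 0
and the result is flagged). Distribution-valued annotations (posteriors,
imported `*.set.prob` comments) are first reduced to the majority state,
lexicographic on ties.

The **type-1 map** is the annotated tree contracted along state-constant
edges: one map node per event, parented by the nearest ancestral event or
the root. The **type-2 collapse** merges sibling map nodes with the same
child state (their parent state is shared by construction): counts sum,
member sets union, the representative distance takes the minimum — the
minimum, rather than a mean, because the full member set is stored on the
node and any other summary remains recoverable. The merge recurses top-
down so children of merged nodes are merged against each other. The
**type-3 collapse** folds *all* nodes representing the same transition
`i -> j` into one: the map is walked top-down with a global
`(parent state, state)` key; the first occurrence creates the merged node
under its (already merged) parent, later occurrences fold in and re-route
their children, which re-merge by the same rule. The one-sentence
description of this level leaves the recursion implicit; this fold is the
unique top-down completion that keeps the result a well-formed tree, and
it conserves total counts by construction (a 500-fixture conservation
suite checks events = matrix total = type-1 size = type-2 counts = type-3
counts).

**Relative rates.** The count matrix is normalized by the total event
count and divided by a state prior: `rate(i, j) = (n_ij / N) / pi_j`.
Dividing by the *destination* prior is a documented choice — the phrase
"divided by state priors" is genuinely ambiguous — and the divisor is
isolated behind the `denominator` argument (`"target"`, `"source"`,
`"product"`) so alternates are one flag away.

**Path queries.** Each root-to-leaf path is compressed (consecutive
duplicate states removed); a whitespace-separated pattern matches a path
when it matches a *contiguous* subsequence of the compressed sequence,
with `*` matching any, possibly empty, run of states. Matching is
unanchored, so `"* X"` finds every path that ever reaches `X`. The
implementation is a small token matcher, tested exactly against a regular
expression oracle.

**Ambiguity filter.** A node is ambiguous when at least two states have
posterior at or above `(1 - f) * p_max`; the default `f = 0.4` retains
states within 40% of the MAP probability, and `f = 0` degenerates to
exact ties. **Sz** is the number of leaves below a node sharing its
state, computed in one bottom-up pass.

## Comparison across methods

Methods are compared on majority states, so probabilistic and
deterministic reconstructions are commensurable. `discrepant_nodes()`
compares internal nodes by default — tips are shared inputs, so counting
them would only dilute the summary; `include_tips = TRUE` restores them.
Transition-map compatibility keys each map node by its full root-to-node
state sequence (path-consistent structure), with a local
`(parent state, state)` key available behind a flag; the shared relation
is reflexive and symmetric by construction and tested as such.

## The simulator, and what the tests do and do not show

`sim_yule_tree()` is a pure-birth simulation: two lineages leave the root
at time zero; while `k < n` are extant a waiting time `Exp(k * birth)`
elapses and a uniformly chosen lineage splits; a final `Exp(n * birth)`
wait places all tips on a common horizon. The root-to-tip height is then
exactly $\sum_{k=2}^{n} \mathrm{Exp}(k\lambda)$, giving the closed-form
mean $(1/\lambda)\sum_{k=2}^{n} 1/k$ used as the statistical oracle.
`simulate_character()` draws the root state from the priors and evolves
every edge by the model's own transition matrix, returning both tip data
and full ancestral truth, so parameter- and state-recovery can be scored.

What this emulates: clean Yule topologies, ultrametric depths, a
stationary homogeneous character. What it does not: non-ultrametric or
misestimated branch lengths, rate variation across lineages, sampling
biases, label errors — all common in real data. Passing recovery tests
therefore demonstrate correctness of the algorithms under the model's own
assumptions, not robustness to their violation.

Problem sizes used by the shipped suite, chosen to keep a full run around
a minute while exercising every code path: exhaustive oracles on trees of
3–5 tips with 2–4 states (every internal labeling enumerated);
conservation and query oracles on 500 and 200 random fixtures; scaling
recovery on twenty 200-leaf trees at true $\sigma = 2$ (fitted within
±50% in at least 80% of replicates); MAP accuracy monotonicity over
$\sigma \in \{0.1, 1, 10\}$ with 50 replicates each on 60-leaf trees.

## Known limitations

* One character per run; the CLI can loop over columns but no joint
  multi-character model is attempted.
* No rate heterogeneity, no general transition-rate matrices (GTR-like
  models), no Bayesian machinery — the F81-like family only, with
  Jukes–Cantor as its equal-frequency special case.
* Sankoff *weighted* cost matrices are not exposed, although the internal
  dynamic program would support them.
* Newick labels survive round trips verbatim except that spaces inside
  quoted labels are normalized to underscores on write; underscores are
  never converted back to spaces.
* SVG output is a deterministic static drawing; interactive exploration
  (zooming, linked highlighting between tree and map) is out of scope.
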