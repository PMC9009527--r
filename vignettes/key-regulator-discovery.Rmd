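---
title: "Key-regulator discovery by hierarchical motif decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key-regulator discovery by hierarchical motif decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubtrace)
```

## The method

`hubtrace` implements a key-regulator discovery pipeline for protein–protein
interaction (PPI) networks. The reasoning chain is:

1. **Topology.** Characterize the curated network by its degree
   distribution $P(k)$, degree-dependent clustering $C(k)$, neighborhood
   connectivity $C_N(k)$, and closeness / betweenness / eigenvector
   centralities. A power law $P(k) \sim k^{-\gamma}$ together with
   $C(k) \sim k^{-\alpha}$ marks a *hierarchical scale-free* topology:
   modules nested inside modules, with hubs knitting them together.
2. **Decomposition.** Recursively split the network into communities by
   Louvain modularity optimization, re-running on each community's induced
   subgraph. A community qualifies for further splitting only if it
   contains at least one triangle — the motif $G(3,3)$ — and recursion
   terminates at triangles, at triangle-free communities, or at
   communities that refuse to split.
3. **Hub tracing.** Select the top-degree hubs (tie-inclusive) and follow
   each through its chain of nested communities. A hub whose chain
   reaches a terminal triangle at the tree's maximum depth is represented
   at *every* organizational scale: a **key regulator**.
4. **Quantitative filter.** Independently, filter a replicate ratio table
   for deregulated proteins: fold change $\ge 1.5$
   ($|\log_2 \mathrm{FC}| \ge 0.585$) *and* $p \le 0.05$ from a two-sample
   t-test on log2 ratios.
5. **Intersection.** Intersect the key-regulator list, the deregulated
   list, and any external candidate lists; the common elements are the
   nominated targets.

Every stage is exercised against synthetic generators with known ground
truth, so the pipeline is testable end to end without external data.

## A worked example

A planted three-level hierarchy: 4 blocks × 3 leaves × 6 nodes, each leaf
two triangles joined by a matching (a triangular prism), with 15
designated regulator hubs.

```{r}
gen <- make_planted_hierarchy()   # defaults: 72 nodes, 15 regulators, seed 7
net <- gen$network
tree <- decompose(net, seed = 42)
tree
level_summary(tree)
```

The decomposition recovers the planted design: depth 3, with
4 → 12 → 24 communities and all 24 terminal motifs. Membership agreement
with the planted truth is perfect at every level:

```{r}
sapply(1:3, function(l) {
  truth <- gen$truth[[paste0("level", l)]]
  membership_agreement(tree_membership(tree, l),
                       setNames(as.character(truth), names(truth)))
})
```

Tracing the top 15 hubs recovers exactly the planted regulators:

```{r}
report <- trace_hubs(tree, select_hubs(net, top_n = 15))
setequal(key_regulators(report), gen$truth$regulators)
```

The quantitative branch, on a synthetic table shaped like the study's
data (434 proteins, 65 planted deregulated, 49 up / 16 down):

```{r}
qt <- make_quant_table()          # seed 3
de <- select_deregulated(qt$table, c("case", "control"))
de
tp <- sum(de$protein_id %in% qt$truth$protein_id)
c(sensitivity = tp / nrow(qt$truth),
  fdp = (nrow(de) - tp) / nrow(de))
```

## Design notes

### Conventions taken from the source protocol

* **Closeness** uses the printed equation $C_C(i) = n / \sum_j d_{ij}$
  with $n$ the size of $i$'s connected component (not the conventional
  $n-1$).
* **Normalized betweenness** divides raw betweenness over unordered pairs
  by $M = (n-1)(n-2)/2$.
* **Local clustering** $c_i$ is defined as 0 for $k_i < 2$.
* The **deregulation filter** uses raw $p \le 0.05$ (no multiple-testing
  correction by default; Benjamini–Hochberg is a switch), and Student's
  pooled-variance t-test on log2 ratios. At three replicates per side,
  Welch's form is conservative (empirical size ≈ 0.034 at the 0.05
  level in our null simulations), while Student's form is exact under
  the equal-variance log-normal null (measured 0.0497 over 100,000 null
  tests); Welch remains available via `var_equal = FALSE`.
* **Hub selection** implements both readings of "top 65 highest degree
  nodes (degree k ≥ 65)": a tie-inclusive `top_n` rule (default) and a
  `min_degree` threshold.

### Community detection: restarts and refinement

Louvain is order-dependent, so `detect_communities()` and `decompose()`
are seeded; sub-community seeds derive arithmetically from the parent
seed, making the whole tree reproducible from one integer. Two
robustness measures are part of the method, not optional tuning:

* **Multi-restart.** A single Louvain run can return a modularity-0
  local optimum: on a 6-node triangular prism it frequently returns the
  three matching pairs ($Q = 0$) instead of the two triangles
  ($Q = 1/6$). We keep the best of 10 seeded restarts.
* **Greedy refinement.** igraph's aggregation phase can lock in
  partitions that a single node move still improves: on a 9-cycle only
  ~3.5% of seeds reach the optimal 3+3+3 arc partition ($Q = 1/3$). A
  deterministic single-node-move pass (strict modularity increase only)
  runs after the best restart.

With both, every partition on graphs small enough to enumerate
exhaustively ($n \le 10$, via restricted-growth-string enumeration of all
set partitions) reaches at least 0.95× — in all our test graphs,
exactly — the true maximum modularity.

### The planted-hierarchy generator

The generator's contract includes *recoverability*: at the stated
defaults, `decompose()` must recover the planted depth and memberships,
and `trace_hubs()` the planted regulators. At desk scale (72 nodes) this
is a sharp constraint. Louvain's resolution window is narrow: the
preferred internal-edge scale is of order $\sqrt{2m}$, so diffuse
random coupling between modules either fragments the top-level blocks or
blurs the leaf partition. The construction therefore uses concentrated,
budgeted coupling rather than i.i.d. block densities:

* leaf pairs inside a block are joined by exactly one **connector** edge,
  placed load-balanced on non-regulator endpoints;
* regulators gain their degree margin through a **rich club** — a cycle
  among each block's regulators plus one global ring — which mirrors the
  empirical rich-club behavior of real PPI hubs and adds ~3× less
  cross-module edge mass per unit of degree than uniform attachment;
* each regulator sends one cyclic **anchor** edge into a regulator-free
  triangle of the next leaf of its home block;
* background noise (`p_out`) is confined to cross-block pairs, capped at
  one extra edge per node, with regulators excluded, which makes the
  "regulators are the top-degree hubs" contract deterministic rather
  than probabilistic.

This design recovers the planted structure exactly — depth 3, membership
agreement 1.0, all 15 regulators, zero false positives — on 100 of 100
generator seeds, not only the default.

### Limitations

* The decomposition is hard-partitioned: no overlapping communities, no
  weighted modularity.
* The quantitative branch models ratio tables only; no spectra,
  peptide-level inference, or isobaric-tag corrections.
* The generator's planted hierarchy is three levels deep by
  construction; deeper designs would need the same margin engineering at
  each additional scale.
* Published headline numbers that depend on the original study's network
  (which is not deposited) are treated as generator shapes, not
  reproduction targets.
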