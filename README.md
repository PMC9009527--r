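# hubtrace

Key-regulator discovery in protein–protein interaction (PPI) networks by
hierarchical motif decomposition.

The package implements a complete, testable pipeline:

1. **Topology** — degree spectra P(k), C(k), C_N(k); closeness,
   betweenness, and eigenvector centralities; log–log power-law fits and
   scale-free / hierarchical classification.
2. **Decomposition** — recursive Louvain community detection on induced
   subgraphs, qualified by the triangle motif G(3,3), down to terminal
   triangles.
3. **Key regulators** — tie-inclusive top-degree hub selection, and
   tracing of each hub through every hierarchical level; hubs whose chain
   ends in a terminal motif at maximum depth are key regulators.
4. **Deregulation filter** — fold change ≥ 1.5 (|log2 FC| ≥ 0.585) AND
   p ≤ 0.05 (t-test on log2 replicate ratios) on quantitation tables.
5. **Intersection** — common candidates across key-regulator, deregulated,
   and external lists.

Synthetic generators (deterministic hierarchical model, planted 3-level
hierarchy with designated regulator hubs, random / preferential-attachment
controls, quantitation tables with planted deregulation) provide ground
truth for every stage.

## Worked example

```r
library(hubtrace)

gen  <- make_planted_hierarchy()     # 72 nodes, 164 edges, 15 planted regulators (seed 7)
tree <- decompose(gen$network, seed = 42)
tree
#> community tree: 72 graph nodes, depth 3, 40 tree nodes (24 motifs G(3,3))

level_summary(tree)
#>   level n_communities min_size max_size n_qualifying n_motifs
#> 1     1             4       18       18            4        0
#> 2     2            12        6        6           12        0
#> 3     3            24        3        3           24       24

report <- trace_hubs(tree, select_hubs(gen$network, top_n = 15))
setequal(key_regulators(report), gen$truth$regulators)
#> TRUE            # all 15 planted regulators, zero false positives

qt <- make_quant_table()             # 434 proteins, 65 planted deregulated (seed 3)
de <- select_deregulated(qt$table, c("case", "control"))
de
#> deregulated proteins (case vs control): 62 selected (46 up, 16 down)
#>   at fold >= 1.5, p <= 0.05
# sensitivity 0.954, false-discovery proportion 0.000 against planted truth
```

On the canonical deterministic hierarchical network (5-node replication,
4 iterations, 625 nodes) the fitted C(k) exponent is **1.109**
(R² = 0.995), matching the expected C(k) ~ 1/k hierarchical law; the
measured type-I error of the p ≤ 0.05 filter over 100,000 null tests is
**0.0497**.

## Repository layout

- `R/` — the package (graph I/O, topology, hierarchy, key regulators,
  quant filter, synthetic data, pipeline orchestration).
- `analysis/01_*.R … 06_*.R` — numbered narrative drivers that run the
  full study on synthetic data, writing to `results/`.
- `tests/testthat/` — unit, property, and acceptance tests, including
  brute-force oracles (Floyd–Warshall distances, path-count betweenness,
  dense eigendecomposition, exhaustive modularity over all set
  partitions, permutation t-test).
- `scripts/acceptance.R` — headline-quantity dump as JSON.
- `vignettes/key-regulator-discovery.Rmd` — methods and design notes.

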