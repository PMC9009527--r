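#!/usr/bin/env Rscript
# 01 — Generate the synthetic study bundle.
#
# Everything downstream works from files written here: a planted 3-level
# hierarchical network with 15 designated regulator hubs (the desk-scale
# stand-in for the arthritic PPI network), a deterministic hierarchical
# network for the C(k) ~ 1/k law, random/preferential-attachment controls,
# and a quantitation table with 65 planted deregulated proteins (49 up,
# 16 down) out of 434 — the study's shape.

library(hubtrace)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

planted <- make_planted_hierarchy()            # seed 7, 72 nodes, 15 regulators
write_network(planted$network, file.path(out, "planted_network.tsv"))
write_truth(planted, file.path(out, "planted_truth.json"))

rb <- make_deterministic_hierarchical(4)       # 625 nodes, no randomness
write_network(rb$network, file.path(out, "hierarchical_network.tsv"))

er <- make_control("random", n = 500, param = 0.02, seed = 1)
pa <- make_control("preferential_attachment", n = 500, param = 2, seed = 1)
write_network(curate(er$network), file.path(out, "control_random.tsv"))
write_network(pa$network, file.path(out, "control_pa.tsv"))

qt <- make_quant_table()                       # seed 3, 434 proteins
write_quant_table(qt, file.path(out, "quant_table.tsv"))
write_truth(qt, file.path(out, "quant_truth.json"))

cat("planted:", igraph::vcount(planted$network), "nodes,",
    igraph::ecount(planted$network), "edges;",
    length(planted$truth$regulators), "regulators\n")
cat("hierarchical:", igraph::vcount(rb$network), "nodes\n")
cat("quant table:", qt$params$n_proteins, "proteins,",
    qt$params$n_deregulated, "planted deregulated\n")
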