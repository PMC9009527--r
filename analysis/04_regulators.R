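#!/usr/bin/env Rscript
# 04 — Hub selection and key-regulator tracing.
#
# Select top-degree hubs (tie-inclusive) and trace each through every
# level of the community tree; hubs whose chain ends in a terminal
# triangle motif at maximum depth are the key regulators. On the planted
# network this should recover exactly the 15 designated regulators with
# no false positives. Also fits per-level power-law exponents for the
# level-1 communities.

library(hubtrace)

data_dir <- file.path("results", "data")
out <- file.path("results", "regulators")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

net <- curate(read_edge_list(file.path(data_dir, "planted_network.tsv")))
tree <- decompose(net, seed = 42)
hubs <- select_hubs(net, top_n = 15)
report <- trace_hubs(tree, hubs)
write_report(report, file.path(out, "key_regulators.tsv"), format = "tsv")
write_report(report, file.path(out, "key_regulators.json"), format = "json")

exps <- per_level_exponents(tree, net)
write.table(exps, file.path(out, "per_level_exponents.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(data_dir, "planted_truth.json"))
planted <- unlist(truth$truth$regulators)
recovered <- key_regulators(report)
cat("hubs selected:", nrow(hubs), "\n")
cat("key regulators:", length(recovered), "of", length(planted),
    "planted;", length(setdiff(recovered, planted)), "false positives\n")
cat("recovered:", paste(sort(recovered), collapse = " "), "\n")
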