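#!/usr/bin/env Rscript
# 05 — Deregulation filter on the quantitation table.
#
# Applies the study's filter — fold change >= 1.5 (|log2 FC| >= 0.585) AND
# p <= 0.05 (Student's t on log2 ratios) — to the synthetic table with 65
# planted deregulated proteins, and scores recovery against ground truth.

library(hubtrace)

data_dir <- file.path("results", "data")
out <- file.path("results", "deregulated")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read.delim(file.path(data_dir, "quant_table.tsv"))
de <- select_deregulated(tab, c("case", "control"))
write_de_list(de, file.path(out, "deregulated.tsv"))

truth <- jsonlite::read_json(file.path(data_dir, "quant_truth.json"),
                             simplifyVector = TRUE)
planted <- truth$truth$protein_id
tp <- sum(de$protein_id %in% planted)
cat(sprintf("selected %d proteins (%d up, %d down)\n", nrow(de),
            attr(de, "n_up"), attr(de, "n_down")))
cat(sprintf("sensitivity %.3f, false-discovery proportion %.3f\n",
            tp / length(planted), (nrow(de) - tp) / max(nrow(de), 1)))
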