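#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — four expression matrices (mRNA,
# lncRNA, circRNA, miRNA) for 3 patient vs 3 control paired samples, a
# miRNA-target map, a gene-set annotation and a qPCR plate, all with known
# ground truth — and write them under results/sim/.

suppressPackageStartupMessages(library(cernet))

cfg <- sim_config(seed = 101)
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

sim <- simulate_expression(cfg)
for (cl in names(sim$matrices))
  write_expression_tsv(sim$matrices[[cl]],
                       file.path("results/sim", paste0("expr_", cl, ".tsv")))
write_metadata_tsv(sim$meta, "results/sim/metadata.tsv")
write_target_map_tsv(simulate_target_map(cfg, sim$truth),
                     "results/sim/target_map.tsv")
write_gmt(simulate_annotation(cfg, sim$truth), "results/sim/annotation.gmt")
write_ct_tsv(simulate_qpcr(cfg, sim$truth), "results/sim/qpcr_ct.tsv")

# ground truth, for the recovery summaries of later stages
truth_de <- do.call(rbind, lapply(names(sim$truth$de_labels), function(cl)
  data.frame(feature = names(sim$truth$de_labels[[cl]]), class = cl,
             label = unname(sim$truth$de_labels[[cl]]))))
write.table(truth_de, "results/sim/truth_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$truth$triplets, "results/sim/truth_triplets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d samples x {%s} features; planted %d DE features and %d triplets",
  nrow(sim$meta),
  paste(vapply(sim$matrices, nrow, 1L), collapse = ", "),
  sum(truth_de$label != "null"), nrow(sim$truth$triplets)))
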