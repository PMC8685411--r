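#!/usr/bin/env Rscript
# Stage 4: ceRNA triplet assembly. Applies the expression filters (group
# mean > 0.5 in at least one group; detected in >= 2/3 of samples), keeps
# positively coexpressed sponge-mRNA pairs, and joins them through shared
# miRNA targeting. Exports the triplet table and the lncRNA- and
# circRNA-anchored networks (SIF, GraphML, node/edge TSV).

suppressPackageStartupMessages(library(cernet))

meta <- read_metadata_tsv("results/sim/metadata.tsv")
classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
mats <- lapply(setNames(classes, classes), function(cl)
  read_expression_tsv(file.path("results/sim", paste0("expr_", cl, ".tsv"))))
de <- lapply(setNames(classes, classes), function(cl)
  read_de_tsv(file.path("results", paste0("de_", cl, ".tsv"))))
pairs <- rbind(read.delim("results/coexpr_lncRNA.tsv"),
               read.delim("results/coexpr_circRNA.tsv"))
targets <- read_target_map_tsv("results/sim/target_map.tsv")

triplets <- find_triplets(pairs, targets, de, mats, meta)
write.table(triplets, "results/triplets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/sim/truth_triplets.tsv")
key <- function(d) paste(d$sponge, d$mirna, d$mrna)
message(sprintf("%d triplets assembled; %d/%d planted triplets recovered",
                nrow(triplets), sum(key(truth) %in% key(triplets)),
                nrow(truth)))

for (cl in c("lncRNA", "circRNA")) {
  tr <- triplets[triplets$sponge_class == cl, ]
  if (nrow(tr) == 0) { message(cl, ": no triplets, no network"); next }
  g <- build_network(tr)
  export_network(g, file.path("results", paste0("network_", cl)))
  s <- network_summary(g)
  message(sprintf("%s network: %d triplets over %d sponges, %d miRNAs, %d mRNAs",
                  cl, s$n_triplets, s$n_sponges, s$n_mirnas, s$n_mrnas))
}
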