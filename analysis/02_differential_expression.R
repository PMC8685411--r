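#!/usr/bin/env Rscript
# Stage 2: paired-t differential expression per RNA class with BH
# correction, thresholds |log2FC| >= 1 and p < 0.05. Writes per-class DE
# tables and the up/down tally to results/.

suppressPackageStartupMessages(library(cernet))

meta <- read_metadata_tsv("results/sim/metadata.tsv")
classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
counts <- NULL
for (cl in classes) {
  mat <- read_expression_tsv(file.path("results/sim", paste0("expr_", cl, ".tsv")))
  de <- call_de(mat, meta, cl)
  write_de_tsv(de, file.path("results", paste0("de_", cl, ".tsv")))
  counts <- rbind(counts, cbind(class = cl, de_summary(de)))
}
write.table(counts, "results/de_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/sim/truth_de.tsv")
for (i in seq_len(nrow(counts))) {
  cl <- counts$class[i]
  de <- read_de_tsv(file.path("results", paste0("de_", cl, ".tsv")))
  tr <- truth[truth$class == cl, ]
  planted <- tr$feature[tr$label != "null"]
  sens <- if (length(planted)) mean(planted %in% de$feature[de$passes]) else NA
  message(sprintf("%-8s: %3d DE (%d up / %d down); planted-DE sensitivity %.2f",
                  cl, counts$total[i], counts$up[i], counts$down[i], sens))
}
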