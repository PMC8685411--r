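#!/usr/bin/env Rscript
# Stage 3: Pearson coexpression screen of DE lncRNA/circRNA against DE
# mRNAs over all six samples, keeping |r| >= 0.8 with correlation-test
# p < 0.05 (exact t-distribution, 4 df). Writes the surviving pairs per
# sponge class, ranked by p as in a top-coexpressed table.

suppressPackageStartupMessages(library(cernet))

meta <- read_metadata_tsv("results/sim/metadata.tsv")
mats <- lapply(c(mRNA = "mRNA", lncRNA = "lncRNA", circRNA = "circRNA"),
               function(cl) read_expression_tsv(
                 file.path("results/sim", paste0("expr_", cl, ".tsv"))))
de <- lapply(c(mRNA = "mRNA", lncRNA = "lncRNA", circRNA = "circRNA"),
             function(cl) read_de_tsv(file.path("results", paste0("de_", cl, ".tsv"))))

for (cl in c("lncRNA", "circRNA")) {
  pairs <- coexpression_pairs(de[[cl]], de$mRNA, mats[[cl]], mats$mRNA)
  write.table(pairs, file.path("results", paste0("coexpr_", cl, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d coexpressed pairs (top p = %.3g, %d positive / %d negative)",
                  cl, nrow(pairs), if (nrow(pairs)) pairs$p[1] else NA,
                  sum(pairs$r > 0), sum(pairs$r < 0)))
}
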