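#!/usr/bin/env Rscript
# Stage 5: hypergeometric over-representation analysis of the DE mRNA set
# against the gene-set annotation, BH-corrected, reporting the top terms.

suppressPackageStartupMessages(library(cernet))

de_mrna <- read_de_tsv("results/de_mRNA.tsv")
ann <- read_gmt("results/sim/annotation.gmt")
universe <- intersect(de_mrna$feature, unique(unlist(ann$members)))
de_set <- intersect(de_mrna$feature[de_mrna$passes], universe)

res <- ora(de_set, universe, ann)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- top_terms(res, 5)
message(sprintf("ORA over %d terms (universe %d, DE set %d); top term: %s (p = %.3g, q = %.3g)",
                nrow(res), res$N[1], res$n[1], top$term[1], top$p[1], top$q[1]))
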