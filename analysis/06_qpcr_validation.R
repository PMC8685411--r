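#!/usr/bin/env Rscript
# Stage 6: qPCR validation analysis. Relative expression by 2^-dCt
# normalized to the reference gene, then a two-tailed Student's t-test per
# assayed ncRNA between the patient and control groups.

suppressPackageStartupMessages(library(cernet))

ct <- read_ct_tsv("results/sim/qpcr_ct.tsv")
res <- qpcr_analysis(ct)
write.table(res, "results/qpcr_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/sim/truth_de.tsv")
for (i in seq_len(nrow(res))) {
  lab <- truth$label[truth$feature == res$gene[i]]
  message(sprintf(
    "%s: 2^-dCt %.3g +/- %.2g (A) vs %.3g +/- %.2g (H), p = %.3g, %s (planted: %s)",
    res$gene[i], res$mean_a[i], res$sd_a[i], res$mean_h[i], res$sd_h[i],
    res$p[i], res$direction[i], lab))
}
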