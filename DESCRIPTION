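Package: cernet
Title: Competing Endogenous RNA Network Inference from Multi-Class
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA and circRNA-miRNA-mRNA competing
    endogenous RNA (ceRNA) networks from normalized expression matrices of
    four RNA classes measured in two groups. Provides paired-t differential
    expression with Benjamini-Hochberg correction and fold-change
    thresholds, exact Pearson correlation tests for coexpression screening,
    expression-level and detection-rate filters, shared-miRNA triplet
    assembly, hypergeometric over-representation analysis against GMT gene
    sets, and qPCR 2^-dCt relative quantification. A synthetic-data
    generator with planted differential expression and planted ceRNA
    triplets supports calibration and recovery testing of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
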