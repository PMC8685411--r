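# shared fixtures: a small simulation config, a deterministic toy matrix
# builder, and a brute-force ceRNA triplet enumerator used as an oracle

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    features_per_class = c(mRNA = 60, lncRNA = 40, circRNA = 30, miRNA = 20),
    de_fraction = 0.2, n_triplets = 3, n_terms = 8, seed = seed
  ), list(...))
  do.call(sim_config, args)
}

# printed correlation/p rows of the study's top-10 coexpression tables,
# reference points for the exact correlation test at n = 6
lnc_rows <- data.frame(
  r = c(0.999831904, 0.999703934, 0.999386649, 0.999334139, 0.999291708,
        0.99915166, -0.999098307, 0.999078497, -0.999071158, -0.999019135),
  p = c(4.238179e-08, 1.314697e-07, 5.641832e-07, 6.649095e-07, 7.523386e-07,
        1.079217e-06, 1.219210e-06, 1.273359e-06, 1.293721e-06, 1.442671e-06))
circ_rows <- data.frame(
  r = c(0.999964542, -0.999961141, -0.999961141, -0.999961141, 0.999960282,
        -0.999922482, 0.999890505, 0.999885106, -0.999882106, 0.999870383),
  p = c(1.885840e-09, 2.264999e-09, 2.264999e-09, 2.264999e-09, 2.366303e-09,
        9.013400e-09, 1.798301e-08, 1.980009e-08, 2.084761e-08, 2.519985e-08))

toy_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features), byrow = TRUE,
         dimnames = list(features, samples))
}

toy_meta <- function(n_per_group = 3) {
  data.frame(sample = c(paste0("A", 1:n_per_group), paste0("H", 1:n_per_group)),
             group = rep(c("A", "H"), each = n_per_group),
             pair = rep(paste0("P", 1:n_per_group), 2),
             stringsAsFactors = FALSE)
}

expect_rel <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * abs(y)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(x - y) / abs(y)), tol))
}

# independent enumerator: checks every (sponge, miRNA, mRNA) combination
# directly against the triplet definition, ignoring the package's indexing
brute_force_triplets <- function(pairs, targets, de_tables, matrices, meta,
                                 filters = filter_config()) {
  keep <- lapply(matrices, expression_filter, meta = meta, config = filters)
  found <- character(0)
  for (cl in setdiff(names(de_tables), c("mRNA", "miRNA"))) {
    de_s <- de_tables[[cl]]; de_g <- de_tables$mRNA
    for (s in de_s$feature) for (g in de_g$feature) for (m in unique(targets$mirna)) {
      ok <- de_s$passes[de_s$feature == s] &&
        de_g$passes[de_g$feature == g] &&
        s %in% keep[[cl]] && g %in% keep$mRNA &&
        any(pairs$ncrna == s & pairs$mrna == g & pairs$r > 0) &&
        any(targets$mirna == m & targets$target == s & targets$target_class == cl) &&
        any(targets$mirna == m & targets$target == g & targets$target_class == "mRNA")
      if (ok) found <- c(found, paste(s, m, g))
    }
  }
  sort(found)
}
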