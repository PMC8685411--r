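test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_target_map(cfg, a$truth),
                   simulate_target_map(cfg, b$truth))
  expect_identical(simulate_annotation(cfg, a$truth),
                   simulate_annotation(cfg, b$truth))
  expect_identical(simulate_qpcr(cfg, a$truth),
                   simulate_qpcr(cfg, b$truth))
})

test_that("expression values are strictly positive and labeled correctly", {
  sim <- simulate_expression(small_config(seed = 3))
  for (m in sim$matrices) expect_true(all(m > 0))
  for (cl in names(sim$truth$de_labels))
    expect_setequal(names(sim$truth$de_labels[[cl]]),
                    rownames(sim$matrices[[cl]]))
  # every planted triplet references features present in the matrices
  tr <- sim$truth$triplets
  expect_true(all(tr$mrna %in% rownames(sim$matrices$mRNA)))
  expect_true(all(tr$mirna %in% rownames(sim$matrices$miRNA)))
  for (i in seq_len(nrow(tr)))
    expect_true(tr$sponge[i] %in% rownames(sim$matrices[[tr$sponge_class[i]]]))
})

test_that("de_fraction = 0 plants no effects", {
  cfg <- small_config(seed = 5, de_fraction = 0, n_triplets = 0)
  sim <- simulate_expression(cfg)
  for (lab in sim$truth$de_labels) expect_true(all(lab == "null"))
})

test_that("zero effect size gives null-calibrated group differences", {
  cfg <- sim_config(features_per_class = c(mRNA = 1000, lncRNA = 0,
                                           circRNA = 0, miRNA = 0),
                    de_fraction = 0.5, effect_log2fc = 0, n_triplets = 0,
                    seed = 11)
  sim <- simulate_expression(cfg)
  m <- log2(sim$matrices$mRNA)
  in_A <- sim$meta$group == "A"
  # oracle: direct per-feature t-tests; labeled "DE" features carry no shift
  pv <- apply(m, 1, function(x) t.test(x[in_A], x[!in_A])$p.value)
  rej <- mean(pv < 0.01)
  se <- sqrt(0.01 * 0.99 / length(pv))
  expect_lt(abs(rej - 0.01), 3 * se + 1e-9)
})

test_that("planted triplets have the promised correlation signs", {
  cfg <- sim_config(features_per_class = c(mRNA = 200, lncRNA = 100,
                                           circRNA = 100, miRNA = 60),
                    de_fraction = 0.3, n_triplets = 20, seed = 9)
  sim <- simulate_expression(cfg)
  tr <- sim$truth$triplets
  r_sm <- r_mm <- r_ms <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    s <- log2(sim$matrices[[tr$sponge_class[i]]][tr$sponge[i], ])
    g <- log2(sim$matrices$mRNA[tr$mrna[i], ])
    m <- log2(sim$matrices$miRNA[tr$mirna[i], ])
    r_sm[i] <- cor(s, g); r_mm[i] <- cor(m, g); r_ms[i] <- cor(m, s)
  }
  expect_gt(mean(r_sm), 0)
  expect_lt(mean(r_mm), 0)
  expect_lt(mean(r_ms), 0)
})

test_that("invalid designs are rejected", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(de_fraction = 1.5), "proportions")
  expect_error(sim_config(coupling_r = 0), "coupling_r")
})

test_that("target map contains all planted edges plus reproducible decoys", {
  cfg <- small_config(seed = 21, n_triplets = 5, decoy_edge_fraction = 0.1)
  sim <- simulate_expression(cfg)
  tm <- simulate_target_map(cfg, sim$truth)
  tr <- sim$truth$triplets
  for (i in seq_len(nrow(tr))) {
    expect_true(any(tm$mirna == tr$mirna[i] & tm$target == tr$sponge[i]))
    expect_true(any(tm$mirna == tr$mirna[i] & tm$target == tr$mrna[i]))
  }
  expect_gte(sum(tm$target_class != "mRNA"), 5)
  expect_gte(sum(tm$target_class == "mRNA"), 5)
  expect_identical(tm, simulate_target_map(cfg, sim$truth))
  expect_false(anyDuplicated(tm) > 0)

  cfg0 <- small_config(seed = 21, n_triplets = 0, decoy_edge_fraction = 0)
  sim0 <- simulate_expression(cfg0)
  expect_identical(nrow(simulate_target_map(cfg0, sim0$truth)), 0L)
})

test_that("annotation plants the most enriched term", {
  cfg <- small_config(seed = 31)
  sim <- simulate_expression(cfg)
  gs <- simulate_annotation(cfg, sim$truth)
  expect_s3_class(gs, "gene_sets")
  expect_true(sim$truth$enriched_term %in% gs$id)
  # oracle: hypergeometric scan over all terms with the true DE set
  universe <- names(sim$truth$de_labels$mRNA)
  de <- universe[sim$truth$de_labels$mRNA != "null"]
  pv <- vapply(gs$members, function(m) {
    k <- length(intersect(m, de))
    phyper(k - 1, length(m), length(universe) - length(m), length(de),
           lower.tail = FALSE)
  }, numeric(1))
  expect_identical(names(which.min(pv)), sim$truth$enriched_term)
  # planted term is >= 80% DE members
  planted <- gs$members[[sim$truth$enriched_term]]
  expect_gte(mean(planted %in% de), 0.8)
})

test_that("n_terms = 0 emits only the enriched term", {
  cfg <- small_config(seed = 8, n_terms = 0)
  sim <- simulate_expression(cfg)
  gs <- simulate_annotation(cfg, sim$truth)
  expect_identical(gs$id, sim$truth$enriched_term)
})

test_that("noiseless qPCR reproduces the planted fold change in dCt exactly", {
  cfg <- small_config(seed = 13, effect_log2fc = 1, noise_log2_sd = 0)
  sim <- simulate_expression(cfg)
  ct <- simulate_qpcr(cfg, sim$truth)
  expect_setequal(unique(ct$sample[ct$gene == "ACTB"]), unique(ct$sample))
  for (g in setdiff(unique(ct$gene), "ACTB")) {
    rel <- relative_expression(ct, g)
    dct_diff <- mean(rel$delta_ct[rel$group == "A"]) -
      mean(rel$delta_ct[rel$group == "H"])
    lab <- sim$truth$de_labels[[if (grepl("^lnc", g)) "lncRNA" else "circRNA"]][[g]]
    expected <- if (lab == "up") -1 else 1
    expect_equal(dct_diff, expected, tolerance = 1e-12)
  }
})
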