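test_that("expression filter applies both screening rules exactly", {
  meta <- toy_meta(3)
  # rows built so exactly 4 satisfy (group mean > 0.5) AND (expressed in
  # >= 2/3 of samples); manual evaluation per row in the comments
  mat <- toy_matrix(c(
    1.0, 1.0, 1.0, 0.1, 0.1, 0.1,   # f01: meanA 1.0 > 0.5, 6/6 expressed -> keep
    0.6, 0.7, 0.5, 0.0, 0.0, 0.0,   # f02: meanA 0.6 > 0.5, 3/6 expressed -> drop
    0.4, 0.4, 0.4, 0.45, 0.45, 0.45,# f03: means 0.4/0.45 -> drop
    0.0, 0.0, 0.0, 2.0, 2.0, 2.0,   # f04: meanH 2 > 0.5, 3/6 -> drop
    0.2, 0.2, 0.2, 1.0, 1.1, 0.9,   # f05: meanH 1.0 > 0.5, 6/6 -> keep
    0.5, 0.5, 0.5, 0.5, 0.5, 0.5,   # f06: means exactly 0.5, not > 0.5 -> drop
    0.0, 1.8, 1.8, 0.1, 0.1, 0.0,   # f07: meanA 1.2 > 0.5, 4/6 >= 2/3 -> keep
    0.0, 0.0, 1.2, 0.0, 0.0, 1.5,   # f08: meanH 0.5 not > 0.5, meanA 0.4 -> drop
    3.0, 3.0, 3.0, 3.0, 3.0, 3.0,   # f09: keep
    0.0, 0.9, 0.9, 0.0, 0.0, 0.9    # f10: meanA 0.6 > 0.5, 3/6 < 2/3 -> drop
  ), sprintf("f%02d", 1:10), meta$sample)
  expect_setequal(expression_filter(mat, meta),
                  c("f01", "f05", "f07", "f09"))
  expect_identical(expression_filter(mat[0, , drop = FALSE], meta),
                   character(0))
})

test_that("the expression filter is monotone in its thresholds", {
  set.seed(33)
  meta <- toy_meta(3)
  mat <- matrix(rexp(50 * 6), 50, 6,
                dimnames = list(sprintf("g%02d", 1:50), meta$sample))
  mat[sample(length(mat), 60)] <- 0
  base <- expression_filter(mat, meta, filter_config(min_group_mean = 0.5))
  for (m in c(0.8, 1.2, 2)) {
    tighter <- expression_filter(mat, meta, filter_config(min_group_mean = m))
    expect_true(all(tighter %in% base))
    base <- tighter
  }
  loose <- expression_filter(mat, meta,
                             filter_config(min_expressed_fraction = 1/3))
  strict <- expression_filter(mat, meta,
                              filter_config(min_expressed_fraction = 1))
  expect_true(all(strict %in% loose))
})

make_toy_run <- function() {
  meta <- toy_meta(3)
  # L1/G1 strongly coexpressed and DE; G2 DE but anticorrelated with L1
  l <- toy_matrix(c(8, 10, 12, 1, 1.2, 0.9), "L1", meta$sample)
  g <- toy_matrix(c(8.2, 10.1, 11.8, 1.1, 1.15, 0.92,
                    1.1, 0.95, 0.9, 8.5, 10.2, 11.7),
                  c("G1", "G2"), meta$sample)
  de_l <- call_de(l, meta, "lncRNA")
  de_g <- call_de(g, meta, "mRNA")
  pairs <- coexpression_pairs(de_l, de_g, l, g)
  list(meta = meta, matrices = list(lncRNA = l, mRNA = g),
       de = list(lncRNA = de_l, mRNA = de_g), pairs = pairs)
}

test_that("a shared miRNA over a positive DE pair yields exactly one triplet", {
  run <- make_toy_run()
  targets <- data.frame(
    mirna = c("m1", "m1", "m1"),
    target = c("L1", "G1", "G2"),
    target_class = c("lncRNA", "mRNA", "mRNA"), stringsAsFactors = FALSE)
  tr <- find_triplets(run$pairs, targets, run$de, run$matrices, run$meta)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$sponge, "L1")
  expect_identical(tr$mirna, "m1")
  expect_identical(tr$mrna, "G1")  # G2 is anticorrelated, r < 0 excluded
  expect_gt(tr$r, 0)
  expect_identical(tr$mirna_direction, "unknown")

  empty <- find_triplets(run$pairs, targets[0, ], run$de, run$matrices,
                         run$meta)
  expect_identical(nrow(empty), 0L)
})

test_that("strict miRNA mode requires an anti-directional DE miRNA", {
  run <- make_toy_run()
  mi <- toy_matrix(c(1, 1.1, 0.9, 8, 10, 12), "m1", run$meta$sample)
  de_mi <- call_de(mi, run$meta, "miRNA")
  de <- c(run$de, list(miRNA = de_mi))
  mats <- c(run$matrices, list(miRNA = mi))
  targets <- data.frame(mirna = "m1", target = c("L1", "G1"),
                        target_class = c("lncRNA", "mRNA"),
                        stringsAsFactors = FALSE)
  tr <- find_triplets(run$pairs, targets, de, mats, run$meta,
                      strict_mirna = TRUE)
  expect_identical(nrow(tr), 1L)  # sponge up, miRNA down: kept
  expect_identical(tr$mirna_direction, "down")
  # flip the miRNA to co-directional: rejected under strict mode
  mi_up <- toy_matrix(c(8, 10, 12, 1, 1.1, 0.9), "m1", run$meta$sample)
  de_up <- c(run$de, list(miRNA = call_de(mi_up, run$meta, "miRNA")))
  tr2 <- find_triplets(run$pairs, targets, de_up,
                       c(run$matrices, list(miRNA = mi_up)), run$meta,
                       strict_mirna = TRUE)
  expect_identical(nrow(tr2), 0L)
})

test_that("triplet assembly agrees with the brute-force enumerator", {
  cfg <- sim_config(features_per_class = c(mRNA = 20, lncRNA = 15,
                                           circRNA = 10, miRNA = 5),
                    de_fraction = 0.4, n_triplets = 2,
                    decoy_edge_fraction = 0.3, seed = 17)
  sim <- simulate_expression(cfg)
  de <- lapply(names(sim$matrices), function(cl)
    call_de(sim$matrices[[cl]], sim$meta, cl))
  names(de) <- names(sim$matrices)
  pairs <- rbind(
    coexpression_pairs(de$lncRNA, de$mRNA, sim$matrices$lncRNA, sim$matrices$mRNA),
    coexpression_pairs(de$circRNA, de$mRNA, sim$matrices$circRNA, sim$matrices$mRNA))
  targets <- simulate_target_map(cfg, sim$truth)
  got <- find_triplets(pairs, targets, de, sim$matrices, sim$meta)
  want <- brute_force_triplets(pairs, targets, de, sim$matrices, sim$meta)
  expect_identical(paste(got$sponge, got$mirna, got$mrna)[
    order(paste(got$sponge, got$mirna, got$mrna))], want)
  # postcondition audit: every emitted triplet passes DE + filters + sharing
  keep <- lapply(sim$matrices, expression_filter, meta = sim$meta)
  for (i in seq_len(nrow(got))) {
    cl <- got$sponge_class[i]
    expect_true(got$sponge[i] %in% intersect(
      de[[cl]]$feature[de[[cl]]$passes], keep[[cl]]))
    expect_true(got$mrna[i] %in% intersect(
      de$mRNA$feature[de$mRNA$passes], keep$mRNA))
    expect_true(any(targets$mirna == got$mirna[i] &
                      targets$target == got$sponge[i]))
    expect_true(any(targets$mirna == got$mirna[i] &
                      targets$target == got$mrna[i]))
    expect_gt(got$r[i], 0)
  }
})

test_that("network construction counts nodes like a set union", {
  tr <- data.frame(
    sponge = c("L1", "L2"), sponge_class = "lncRNA",
    mirna = c("m1", "m1"), mrna = c("G1", "G1"),
    r = c(0.9, 0.85), p = c(0.01, 0.02),
    sponge_direction = c("up", "down"), mrna_direction = "up",
    mirna_direction = "unknown", stringsAsFactors = FALSE)
  g <- build_network(tr)
  s <- network_summary(g)
  expect_identical(s$n_sponges, 2L)
  expect_identical(s$n_mirnas, 1L)
  expect_identical(s$n_mrnas, 1L)
  expect_identical(s$n_nodes, 4L)
  expect_identical(s$n_edges, 5L)  # 2 miRNA-sponge, 1 miRNA-mRNA, 2 coexpr
  # tripartite: no miRNA-miRNA edge, every edge touches its declared types
  ed <- igraph::as_data_frame(g, "edges")
  cls <- setNames(igraph::V(g)$class, igraph::V(g)$name)
  expect_true(all(cls[ed$from] == "miRNA" | cls[ed$to] == "miRNA" |
                    ed$type == "coexpression"))
  empty <- build_network(tr[0, ])
  expect_identical(network_summary(empty)$n_nodes, 0L)
  expect_identical(network_summary(empty)$n_triplets, 0L)
})

test_that("random triplet lists produce counts equal to brute-force recounts", {
  set.seed(71)
  for (i in 1:5) {
    n <- sample(3:12, 1)
    tr <- unique(data.frame(
      sponge = sample(paste0("L", 1:4), n, TRUE), sponge_class = "lncRNA",
      mirna = sample(paste0("m", 1:3), n, TRUE),
      mrna = sample(paste0("G", 1:4), n, TRUE),
      r = runif(n), p = runif(n, 0, 0.05),
      sponge_direction = "up", mrna_direction = "down",
      mirna_direction = "unknown", stringsAsFactors = FALSE))
    # drop ids reused across roles so node attributes stay single-valued
    tr <- tr[!tr$mrna %in% tr$sponge, , drop = FALSE]
    tr <- tr[!duplicated(tr[, c("sponge", "mirna", "mrna")]), , drop = FALSE]
    s <- network_summary(build_network(tr))
    expect_identical(s$n_sponges, length(unique(tr$sponge)))
    expect_identical(s$n_mirnas, length(unique(tr$mirna)))
    expect_identical(s$n_mrnas, length(unique(tr$mrna)))
    expect_identical(s$n_triplets, nrow(tr))
  }
})

test_that("network exports round-trip and match the edge list", {
  run <- make_toy_run()
  targets <- data.frame(mirna = "m1", target = c("L1", "G1"),
                        target_class = c("lncRNA", "mRNA"),
                        stringsAsFactors = FALSE)
  tr <- find_triplets(run$pairs, targets, run$de, run$matrices, run$meta)
  g <- build_network(tr)
  base <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(g, base)
  # SIF: one line per edge
  expect_identical(length(readLines(paths["sif"])),
                   as.integer(igraph::ecount(g)))
  # GraphML: well-formed XML with the GraphML root element
  doc <- xml2::read_xml(paths["graphml"])
  expect_identical(xml2::xml_name(doc), "graphml")
  g_ml <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g_ml), igraph::vcount(g))
  expect_equal(igraph::ecount(g_ml), igraph::ecount(g))
  # TSV pair: lossless round trip
  g2 <- import_network_tsv(paths["nodes"], paths["edges"])
  expect_identical(igraph::as_data_frame(g2, "vertices"),
                   igraph::as_data_frame(g, "vertices"))
  expect_identical(igraph::as_data_frame(g2, "edges")[, c("from", "to", "type")],
                   igraph::as_data_frame(g, "edges")[, c("from", "to", "type")])
  expect_error(export_network(g, base, formats = "dot"), "unknown format")
})
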