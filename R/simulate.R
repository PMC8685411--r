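#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' design the package targets: two groups ("A" = patients, "H" = healthy
#' controls) of `n_per_group = 3` paired samples profiled for mRNA, lncRNA,
#' circRNA and miRNA, log-normal expression with planted differential
#' features at `|log2FC| = effect_log2fc`, and planted ceRNA triplets whose
#' sponge and mRNA are positively coupled while the shared miRNA is
#' negatively coupled to both.
#'
#' @param n_per_group samples per group (>= 2).
#' @param features_per_class named integer vector over
#'   `c("mRNA","lncRNA","circRNA","miRNA")`.
#' @param de_fraction fraction of features per class planted as DE, in
#'   `[0, 1]`.
#' @param effect_log2fc planted absolute log2 fold change (group A vs H).
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of per-feature
#'   baseline expression on the log2 scale.
#' @param noise_log2_sd per-sample log2 measurement noise SD.
#' @param n_triplets number of planted sponge--miRNA--mRNA triplets.
#' @param coupling_r target within-triplet correlation magnitude in
#'   `(0, 1]`; triplet members share a latent per-sample factor whose
#'   loading is chosen so that the expected Pearson correlation between two
#'   coupled members equals `coupling_r`.
#' @param decoy_edge_fraction probability that a non-planted (null) feature
#'   receives a decoy miRNA-target edge in [simulate_target_map()].
#' @param n_terms number of random gene sets in [simulate_annotation()]
#'   (one additional DE-enriched term is always emitted).
#' @param seed integer seed; every generator is deterministic given the
#'   config.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_per_group = 3,
                       features_per_class = c(mRNA = 300, lncRNA = 200,
                                              circRNA = 150, miRNA = 60),
                       de_fraction = 0.1,
                       effect_log2fc = 3,
                       baseline_log2_mean = 3,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       n_triplets = 5,
                       coupling_r = 0.9,
                       decoy_edge_fraction = 0.05,
                       n_terms = 20,
                       seed = 1L) {
  classes <- c("mRNA", "lncRNA", "circRNA", "miRNA")
  if (!is.numeric(n_per_group) || n_per_group < 2)
    stop("invalid design: n_per_group must be >= 2", call. = FALSE)
  if (!all(classes %in% names(features_per_class)))
    stop("features_per_class must name all of: ",
         paste(classes, collapse = ", "), call. = FALSE)
  features_per_class <- features_per_class[classes]
  if (any(features_per_class < 0)) stop("feature counts must be >= 0", call. = FALSE)
  for (p in c(de_fraction = de_fraction, decoy_edge_fraction = decoy_edge_fraction))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (effect_log2fc < 0) stop("effect_log2fc must be >= 0", call. = FALSE)
  if (baseline_log2_sd <= 0) stop("baseline_log2_sd must be > 0", call. = FALSE)
  if (noise_log2_sd < 0) stop("noise_log2_sd must be >= 0", call. = FALSE)
  if (coupling_r <= 0 || coupling_r > 1)
    stop("coupling_r must lie in (0, 1]", call. = FALSE)
  if (n_triplets < 0 || n_terms < 0) stop("counts must be >= 0", call. = FALSE)
  structure(list(
    n_per_group = as.integer(n_per_group),
    features_per_class = as.integer(features_per_class) |>
      setNames(classes),
    de_fraction = de_fraction,
    effect_log2fc = effect_log2fc,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    noise_log2_sd = noise_log2_sd,
    n_triplets = as.integer(n_triplets),
    coupling_r = coupling_r,
    decoy_edge_fraction = decoy_edge_fraction,
    n_terms = as.integer(n_terms),
    seed = as.integer(seed)
  ), class = "sim_config")
}

feature_ids <- function(class, n) {
  prefix <- c(mRNA = "mRNA", lncRNA = "lnc", circRNA = "circ", miRNA = "miR")[[class]]
  if (n == 0) return(character(0))
  sprintf("%s_%04d", prefix, seq_len(n))
}

#' Simulate expression matrices with planted ground truth
#'
#' Draws four features-x-samples matrices (mRNA, lncRNA, circRNA, miRNA)
#' from a log-normal model. Per feature `f` and sample `s` the log2 value is
#' `baseline_f + effect_f * [s in group A] + coupling_f(s) + noise`, where
#' `effect_f` is `+/- effect_log2fc` for planted DE features and 0
#' otherwise. Members of a planted triplet share a per-sample latent factor:
#' the sponge and mRNA load on it positively and the miRNA negatively. The
#' per-sample noise variance of a triplet member is split between the shared
#' factor (a fraction `coupling_r`) and an independent residual, so the
#' expected within-group pairwise correlation magnitude equals `coupling_r`
#' while the total noise SD stays at `noise_log2_sd` for every feature.
#' Matrices are returned on the raw (exponentiated) scale, so all values are
#' strictly positive.
#'
#' The sponge and mRNA of each planted triplet are drawn from the planted DE
#' features and forced to share a direction (so their pooled-sample
#' correlation is positive); the triplet miRNA is left non-DE, mirroring
#' networks in which miRNA regulation status is unknown.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   * `matrices`: named list of numeric matrices (features x samples),
#'   * `meta`: data.frame with columns `sample`, `group` ("A"/"H"), `pair`
#'     (sample i of A is paired with sample i of H),
#'   * `truth`: ground truth with `de_labels` (named vector per class with
#'     values `"up"/"down"/"null"`), `triplets` (data.frame sponge,
#'     sponge_class, mirna, mrna, direction) and `enriched_term`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  classes <- names(config$features_per_class)
  samples <- c(sprintf("A%d", seq_len(n)), sprintf("H%d", seq_len(n)))
  meta <- data.frame(
    sample = samples,
    group = rep(c("A", "H"), each = n),
    pair = rep(sprintf("P%d", seq_len(n)), 2),
    stringsAsFactors = FALSE
  )
  in_A <- meta$group == "A"

  de_labels <- list()
  log2mats <- list()
  for (cl in classes) {
    nf <- config$features_per_class[[cl]]
    ids <- feature_ids(cl, nf)
    n_de <- round(config$de_fraction * nf)
    lab <- rep("null", nf)
    if (n_de > 0) {
      de_idx <- sample.int(nf, n_de)
      lab[de_idx] <- sample(c("up", "down"), n_de, replace = TRUE)
    }
    names(lab) <- ids
    de_labels[[cl]] <- lab
    baseline <- rnorm(nf, config$baseline_log2_mean, config$baseline_log2_sd)
    effect <- ifelse(lab == "up", config$effect_log2fc,
                     ifelse(lab == "down", -config$effect_log2fc, 0))
    m <- matrix(rnorm(nf * 2 * n, sd = config$noise_log2_sd), nf, 2 * n,
                dimnames = list(ids, samples))
    m <- m + baseline + outer(effect, as.numeric(in_A))
    log2mats[[cl]] <- m
  }

  # plant triplets: sponge from DE lncRNA/circRNA (alternating class), mRNA
  # from DE mRNAs, miRNA from null miRNAs; members share a latent factor
  triplets <- data.frame(sponge = character(0), sponge_class = character(0),
                         mirna = character(0), mrna = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
  if (config$n_triplets > 0) {
    de_mrna <- names(de_labels$mRNA)[de_labels$mRNA != "null"]
    avail <- list(
      lncRNA = names(de_labels$lncRNA)[de_labels$lncRNA != "null"],
      circRNA = names(de_labels$circRNA)[de_labels$circRNA != "null"]
    )
    mirna_pool <- names(de_labels$miRNA)[de_labels$miRNA == "null"]
    want_class <- rep(c("lncRNA", "circRNA"), length.out = config$n_triplets)
    if (length(de_mrna) < config$n_triplets ||
        length(mirna_pool) < config$n_triplets ||
        sum(want_class == "lncRNA") > length(avail$lncRNA) ||
        sum(want_class == "circRNA") > length(avail$circRNA))
      stop("not enough planted DE features to host n_triplets triplets; ",
           "raise de_fraction or features_per_class", call. = FALSE)
    mrnas <- sample(de_mrna, config$n_triplets)
    mirnas <- sample(mirna_pool, config$n_triplets)
    sponges <- character(config$n_triplets)
    taken <- character(0)
    for (i in seq_len(config$n_triplets)) {
      pool <- setdiff(avail[[want_class[i]]], taken)
      sponges[i] <- sample(pool, 1)
      taken <- c(taken, sponges[i])
    }
    dirs <- sample(c("up", "down"), config$n_triplets, replace = TRUE)
    triplets <- data.frame(sponge = sponges, sponge_class = want_class,
                           mirna = mirnas, mrna = mrnas, direction = dirs,
                           stringsAsFactors = FALSE)

    # split the per-sample noise variance into a shared latent part and an
    # independent residual so that a^2 / (a^2 + s_res^2) = coupling_r while
    # the total noise SD stays noise_log2_sd
    s <- config$noise_log2_sd
    a <- s * sqrt(config$coupling_r)
    s_res <- s * sqrt(1 - config$coupling_r)
    for (i in seq_len(config$n_triplets)) {
      tr <- triplets[i, ]
      z <- rnorm(2 * n)
      eff <- if (tr$direction == "up") config$effect_log2fc else -config$effect_log2fc
      shift <- eff * as.numeric(in_A)
      regen <- function(mat, id, sign, shifted) {
        base <- rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
        mat[id, ] <- base + (if (shifted) shift else 0) + sign * a * z +
          rnorm(2 * n, sd = s_res)
        mat
      }
      log2mats[[tr$sponge_class]] <- regen(log2mats[[tr$sponge_class]], tr$sponge, +1, TRUE)
      log2mats[["mRNA"]] <- regen(log2mats[["mRNA"]], tr$mrna, +1, TRUE)
      log2mats[["miRNA"]] <- regen(log2mats[["miRNA"]], tr$mirna, -1, FALSE)
      de_labels[[tr$sponge_class]][tr$sponge] <- tr$direction
      de_labels[["mRNA"]][tr$mrna] <- tr$direction
    }
  }

  list(
    matrices = lapply(log2mats, function(m) 2^m),
    meta = meta,
    truth = list(de_labels = de_labels, triplets = triplets,
                 enriched_term = "TERM_ENRICHED")
  )
}

#' Simulate a miRNA-target interaction map
#'
#' Emits the miRNA->sponge and miRNA->mRNA edges of every planted triplet,
#' plus decoy edges: each null (non-DE) mRNA/lncRNA/circRNA feature receives
#' an edge from a uniformly drawn miRNA with probability
#' `decoy_edge_fraction`.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_expression()].
#' @return data.frame with columns `mirna`, `target`, `target_class`; no
#'   duplicate edges.
#' @export
simulate_target_map <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  edges <- list()
  tr <- truth$triplets
  if (nrow(tr) > 0) {
    edges[[1]] <- data.frame(mirna = tr$mirna, target = tr$sponge,
                             target_class = tr$sponge_class, stringsAsFactors = FALSE)
    edges[[2]] <- data.frame(mirna = tr$mirna, target = tr$mrna,
                             target_class = "mRNA", stringsAsFactors = FALSE)
  }
  mirnas <- names(truth$de_labels$miRNA)
  if (config$decoy_edge_fraction > 0 && length(mirnas) > 0) {
    for (cl in c("mRNA", "lncRNA", "circRNA")) {
      nulls <- names(truth$de_labels[[cl]])[truth$de_labels[[cl]] == "null"]
      if (length(nulls) == 0) next
      hit <- stats::runif(length(nulls)) < config$decoy_edge_fraction
      if (!any(hit)) next
      edges[[length(edges) + 1]] <- data.frame(
        mirna = sample(mirnas, sum(hit), replace = TRUE),
        target = nulls[hit], target_class = cl, stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0)
    return(data.frame(mirna = character(0), target = character(0),
                      target_class = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Simulate a gene-set annotation collection
#'
#' Generates `n_terms` random gene sets over the mRNA universe plus one
#' planted term (`truth$enriched_term`) in which at least 80% of members are
#' planted-DE mRNAs, to serve as a positive control for
#' over-representation analysis.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_expression()].
#' @param term_size_range inclusive range random term sizes are drawn from.
#' @return a `gene_sets` object (see [gene_sets()]).
#' @export
simulate_annotation <- function(config, truth, term_size_range = c(10, 30)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  universe <- names(truth$de_labels$mRNA)
  de <- universe[truth$de_labels$mRNA != "null"]
  nulls <- setdiff(universe, de)
  categories <- c("BP", "CC", "MF", "pathway")

  ids <- character(0); names_ <- character(0); cats <- character(0)
  members <- list()
  if (config$n_terms > 0) {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    config$n_terms, replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    for (i in seq_len(config$n_terms)) {
      ids <- c(ids, sprintf("TERM_%04d", i))
      names_ <- c(names_, sprintf("random gene set %d", i))
      cats <- c(cats, sample(categories, 1))
      members[[length(members) + 1]] <- sort(sample(universe, sizes[i]))
    }
  }
  # planted term: >= 80% planted-DE members
  size_e <- min(10, max(2, length(de)))
  n_de_members <- max(1, ceiling(0.8 * size_e))
  n_de_members <- min(n_de_members, length(de))
  filler <- min(size_e - n_de_members, length(nulls))
  ids <- c(ids, truth$enriched_term)
  names_ <- c(names_, "planted DE-enriched set")
  cats <- c(cats, "BP")
  members[[length(members) + 1]] <-
    sort(c(sample(de, n_de_members), if (filler > 0) sample(nulls, filler)))
  gene_sets(ids, names_, cats, members)
}

#' Simulate a qPCR Ct table
#'
#' Generates threshold-cycle (Ct) values for selected features plus a
#' reference gene, from the same planted-effect model as
#' [simulate_expression()]: `Ct = ct_intercept - log2(expression)` plus
#' measurement noise of SD `noise_log2_sd` per replicate. The reference gene
#' is measured in every sample at a fixed abundance, so with zero noise the
#' group difference in dCt equals minus the planted log2 fold change
#' exactly.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_expression()].
#' @param genes features to assay; defaults to the planted triplet sponges
#'   (the ncRNAs one would carry to validation). Ignored features without a
#'   ground-truth label are dropped.
#' @param n_per_group validation cohort size per group; defaults to the
#'   config's. Validation cohorts are typically larger than the discovery
#'   cohort and are simulated as unpaired.
#' @param reference reference-gene id (a housekeeping gene such as actin).
#' @param n_replicates technical replicates per well.
#' @param ct_intercept Ct of a transcript at log2 expression 0.
#' @return data.frame with columns `sample`, `group`, `gene`, `replicate`,
#'   `ct`.
#' @export
simulate_qpcr <- function(config, truth, genes = NULL,
                          n_per_group = config$n_per_group,
                          reference = "ACTB", n_replicates = 2,
                          ct_intercept = 35) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  labels <- unlist(truth$de_labels, use.names = FALSE)
  names(labels) <- unlist(lapply(truth$de_labels, names), use.names = FALSE)
  if (is.null(genes)) genes <- truth$triplets$sponge
  genes <- intersect(genes, names(labels))
  samples <- c(sprintf("VA%d", seq_len(n_per_group)),
               sprintf("VH%d", seq_len(n_per_group)))
  groups <- rep(c("A", "H"), each = n_per_group)
  rows <- list()
  for (g in c(genes, reference)) {
    if (g == reference) {
      log2expr <- rep(config$baseline_log2_mean, length(samples))
    } else {
      eff <- switch(labels[[g]], up = config$effect_log2fc,
                    down = -config$effect_log2fc, 0)
      base <- rnorm(1, config$baseline_log2_mean, config$baseline_log2_sd)
      log2expr <- base + eff * as.numeric(groups == "A")
    }
    for (rep_i in seq_len(n_replicates)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = samples, group = groups, gene = g, replicate = rep_i,
        ct = ct_intercept - log2expr +
          rnorm(length(samples), sd = config$noise_log2_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$sample, out$replicate), ]
  rownames(out) <- NULL
  out
}
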