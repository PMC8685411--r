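#' Pipeline run configuration
#'
#' Bundles the per-stage configurations, stage toggles and output
#' directory. Either the synthetic-data stage generates all inputs
#' (`stages["simulate"]`), or `inputs` supplies paths to expression TSVs,
#' metadata, a target map, a GMT annotation and a Ct table as written by
#' the package's writers.
#'
#' @param sim a [sim_config()].
#' @param thresholds a [threshold_config()].
#' @param filters a [filter_config()].
#' @param r_threshold,p_threshold coexpression-pair thresholds.
#' @param stages named logical over
#'   `c("simulate","de","coexpr","cerna","enrich","qpcr")`.
#' @param inputs named list of input paths (used when `simulate` is off):
#'   `expression` (named list of TSV paths per RNA class), `metadata`,
#'   `targets`, `annotation`, `ct`.
#' @param out_dir directory for stage outputs, or `NULL` to skip writing.
#' @param seed overrides `sim$seed` when given.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = threshold_config(),
                            filters = filter_config(),
                            r_threshold = 0.8, p_threshold = 0.05,
                            stages = c(simulate = TRUE, de = TRUE,
                                       coexpr = TRUE, cerna = TRUE,
                                       enrich = TRUE, qpcr = TRUE),
                            inputs = NULL, out_dir = NULL, seed = NULL) {
  all_stages <- c("simulate", "de", "coexpr", "cerna", "enrich", "qpcr")
  st <- setNames(rep(FALSE, length(all_stages)), all_stages)
  st[names(stages)] <- as.logical(stages)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, thresholds = thresholds, filters = filters,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 stages = st, inputs = inputs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [pipeline_config()] (`sim`, `thresholds`, `filters`, `r_threshold`,
#' `p_threshold`, `stages`, `inputs`, `out_dir`, `seed`); omitted keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$thresholds)) args$thresholds <- do.call(threshold_config, y$thresholds)
  if (!is.null(y$filters)) args$filters <- do.call(filter_config, y$filters)
  for (k in c("r_threshold", "p_threshold", "inputs", "out_dir", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  do.call(pipeline_config, args)
}

stage_require <- function(x, what, stage) {
  if (is.null(x))
    stop("stage '", stage, "' is missing its input: ", what,
         " (enable the producing stage or supply it via inputs)",
         call. = FALSE)
  x
}

#' Run the full ceRNA inference pipeline
#'
#' Executes the enabled stages in order: simulate (or load) the four
#' expression matrices, call DE per RNA class, screen coexpressed
#' DE ncRNA-DE mRNA pairs, assemble ceRNA triplets and the two networks
#' (lncRNA- and circRNA-anchored), run over-representation analysis of the
#' DE mRNAs, and analyze the qPCR table. Identical configurations (and
#' seeds) produce identical reports and identical output files.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [load_pipeline_config()].
#' @return A report list with (per enabled stage) `de` (tables per class),
#'   `de_counts` (class/total/up/down), `pairs` (per sponge class),
#'   `triplets`, `network_summary` (per sponge class), `enrichment`,
#'   `qpcr`, plus `truth` when simulated. Disabled stages are absent; all
#'   stages off gives an empty report.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_tsv_file(df, file.path(out_dir, name))
  }
  report <- list()
  matrices <- NULL; meta <- NULL; truth <- NULL
  targets <- NULL; annotation <- NULL; ct_table <- NULL

  if (st[["simulate"]]) {
    sim <- simulate_expression(config$sim)
    matrices <- sim$matrices; meta <- sim$meta; truth <- sim$truth
    targets <- simulate_target_map(config$sim, truth)
    annotation <- simulate_annotation(config$sim, truth)
    ct_table <- simulate_qpcr(config$sim, truth)
    report$truth <- truth
    if (!is.null(out_dir)) {
      for (cl in names(matrices))
        write_expression_tsv(matrices[[cl]], file.path(out_dir, paste0("expr_", cl, ".tsv")))
      write_metadata_tsv(meta, file.path(out_dir, "metadata.tsv"))
      write_target_map_tsv(targets, file.path(out_dir, "target_map.tsv"))
      write_gmt(annotation, file.path(out_dir, "annotation.gmt"))
      write_ct_tsv(ct_table, file.path(out_dir, "qpcr_ct.tsv"))
    }
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    if (!is.null(ip$expression))
      matrices <- lapply(ip$expression, read_expression_tsv)
    if (!is.null(ip$metadata)) meta <- read_metadata_tsv(ip$metadata)
    if (!is.null(ip$targets)) targets <- read_target_map_tsv(ip$targets)
    if (!is.null(ip$annotation)) annotation <- read_gmt(ip$annotation)
    if (!is.null(ip$ct)) ct_table <- read_ct_tsv(ip$ct)
  }

  de <- NULL
  if (st[["de"]]) {
    stage_require(matrices, "expression matrices", "de")
    stage_require(meta, "sample metadata", "de")
    de <- lapply(names(matrices), function(cl)
      call_de(matrices[[cl]], meta, cl, config$thresholds))
    names(de) <- names(matrices)
    report$de <- de
    counts <- do.call(rbind, lapply(names(de), function(cl)
      cbind(class = cl, de_summary(de[[cl]]))))
    report$de_counts <- counts
    for (cl in names(de)) emit(de[[cl]], paste0("de_", cl, ".tsv"))
    emit(counts, "de_counts.tsv")
  }

  pairs <- NULL
  if (st[["coexpr"]]) {
    stage_require(de, "DE tables", "coexpr")
    pairs <- lapply(c("lncRNA", "circRNA"), function(cl)
      coexpression_pairs(de[[cl]], de$mRNA, matrices[[cl]], matrices$mRNA,
                         config$r_threshold, config$p_threshold,
                         config$thresholds$pseudocount))
    names(pairs) <- c("lncRNA", "circRNA")
    report$pairs <- pairs
    for (cl in names(pairs)) emit(pairs[[cl]], paste0("coexpr_", cl, ".tsv"))
  }

  if (st[["cerna"]]) {
    stage_require(pairs, "coexpression pairs", "cerna")
    stage_require(targets, "miRNA-target map", "cerna")
    all_pairs <- do.call(rbind, pairs)
    triplets <- find_triplets(all_pairs, targets, de, matrices, meta,
                              config$filters)
    report$triplets <- triplets
    emit(triplets, "triplets.tsv")
    report$network_summary <- lapply(
      split(triplets, factor(triplets$sponge_class, c("lncRNA", "circRNA"))),
      function(tr) if (nrow(tr) == 0) NULL else {
        g <- build_network(tr)
        if (!is.null(out_dir))
          export_network(g, file.path(out_dir, paste0(
            "network_", tr$sponge_class[1])))
        network_summary(g)
      })
  }

  if (st[["enrich"]]) {
    stage_require(de, "DE tables", "enrich")
    stage_require(annotation, "gene-set annotation", "enrich")
    universe <- intersect(de$mRNA$feature,
                          unique(unlist(annotation$members)))
    de_set <- intersect(de$mRNA$feature[de$mRNA$passes], universe)
    report$enrichment <- ora(de_set, universe, annotation)
    emit(report$enrichment, "enrichment.tsv")
  }

  if (st[["qpcr"]]) {
    stage_require(ct_table, "qPCR Ct table", "qpcr")
    report$qpcr <- qpcr_analysis(ct_table)
    emit(report$qpcr, "qpcr_results.tsv")
  }

  report
}
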