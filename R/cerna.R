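#' Expression-filter configuration for ceRNA candidates
#'
#' The two screening rules applied before network assembly: at least one
#' group's mean expression must exceed `min_group_mean`, and the feature
#' must be detected (expression strictly above `expressed_threshold`) in at
#' least `min_expressed_fraction` of all samples.
#'
#' @param min_group_mean minimum group mean expression (default 0.5,
#'   normalized expression units).
#' @param min_expressed_fraction minimum fraction of samples in which the
#'   feature is detected (default 2/3).
#' @param expressed_threshold a sample counts as expressing the feature when
#'   its value is strictly greater than this (default 0).
#' @param fc_up,fc_down fold-change bounds equivalent to the log2FC call
#'   (defaults 2 and 0.5, i.e. `|log2FC| >= 1`); `fc_down` defaults to the
#'   reciprocal of `fc_up`.
#' @param p_threshold significance cutoff carried alongside (default 0.05).
#' @return list of class `"filter_config"`.
#' @export
filter_config <- function(min_group_mean = 0.5, min_expressed_fraction = 2/3,
                          expressed_threshold = 0, fc_up = 2,
                          fc_down = 1 / fc_up, p_threshold = 0.05) {
  if (min_expressed_fraction <= 0 || min_expressed_fraction > 1)
    stop("min_expressed_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(min_group_mean = min_group_mean,
                 min_expressed_fraction = min_expressed_fraction,
                 expressed_threshold = expressed_threshold,
                 fc_up = fc_up, fc_down = fc_down, p_threshold = p_threshold),
            class = "filter_config")
}

#' Expression filter
#'
#' Keeps features whose group-A or group-H mean exceeds `min_group_mean`
#' and that are detected in at least `min_expressed_fraction` of all
#' samples. Raising either bound can only shrink the result (the filter is
#' monotone).
#'
#' @param mat features x samples matrix.
#' @param meta sample metadata with `sample` and `group` columns.
#' @param config a [filter_config()].
#' @return character vector of passing feature ids (possibly empty).
#' @export
expression_filter <- function(mat, meta, config = filter_config()) {
  if (nrow(mat) == 0) return(character(0))
  if (!all(c("A", "H") %in% meta$group))
    stop("design error: both groups A and H must be present", call. = FALSE)
  meta <- meta[match(colnames(mat), meta$sample), ]
  mean_A <- rowMeans(mat[, meta$group == "A", drop = FALSE])
  mean_H <- rowMeans(mat[, meta$group == "H", drop = FALSE])
  frac_expr <- rowMeans(mat > config$expressed_threshold)
  keep <- (mean_A > config$min_group_mean | mean_H > config$min_group_mean) &
    frac_expr >= config$min_expressed_fraction
  rownames(mat)[keep]
}

#' Assemble ceRNA triplets from shared miRNA targeting
#'
#' A triplet (sponge, miRNA, mRNA) is emitted iff
#' * the sponge (lncRNA or circRNA) and the mRNA both pass DE calling and
#'   the expression filter,
#' * (sponge, mRNA) is a surviving coexpression pair with `r > 0` (the
#'   ceRNA model predicts positive sponge-target coupling), and
#' * the target map contains both the miRNA->sponge and miRNA->mRNA edge.
#'
#' miRNA DE status is not required: miRNAs absent from (or not passing) the
#' miRNA DE table get direction `"unknown"`. With `strict_mirna = TRUE` the
#' miRNA must itself be DE with direction opposite to the sponge.
#'
#' @param pairs coexpression pairs from [coexpression_pairs()] (one or both
#'   sponge classes; may be the rbind of the lncRNA and circRNA runs).
#' @param targets target map: data.frame with `mirna`, `target`,
#'   `target_class`.
#' @param de_tables named list of DE tables from [call_de()]; must contain
#'   `mRNA` and every sponge class present in `pairs`; `miRNA` optional.
#' @param matrices named list of expression matrices matching `de_tables`.
#' @param meta sample metadata.
#' @param filters a [filter_config()].
#' @param strict_mirna require DE miRNA anti-directional to the sponge.
#' @return data.frame ordered by (mirna, sponge, mrna): `sponge`,
#'   `sponge_class`, `mirna`, `mrna`, `r`, `p`, `sponge_direction`,
#'   `mrna_direction`, `mirna_direction`.
#' @export
find_triplets <- function(pairs, targets, de_tables, matrices, meta,
                          filters = filter_config(), strict_mirna = FALSE) {
  empty <- data.frame(sponge = character(0), sponge_class = character(0),
                      mirna = character(0), mrna = character(0),
                      r = numeric(0), p = numeric(0),
                      sponge_direction = character(0),
                      mrna_direction = character(0),
                      mirna_direction = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0 || nrow(targets) == 0) return(empty)

  keep <- lapply(matrices, expression_filter, meta = meta, config = filters)
  eligible <- function(cl) {
    de <- de_tables[[cl]]
    if (is.null(de)) stop("missing DE table for class ", cl, call. = FALSE)
    intersect(de$feature[de$passes], keep[[cl]])
  }
  dir_of <- function(cl, ids) {
    de <- de_tables[[cl]]
    de$direction[match(ids, de$feature)]
  }
  ok_mrna <- eligible("mRNA")
  mirna_de <- de_tables[["miRNA"]]

  pairs <- pairs[pairs$r > 0, , drop = FALSE]
  rows <- vector("list", nrow(targets))
  n_out <- 0
  for (cl in unique(pairs$ncrna_class)) {
    ok_sponge <- eligible(cl)
    pcl <- pairs[pairs$ncrna_class == cl &
                   pairs$ncrna %in% ok_sponge &
                   pairs$mrna %in% ok_mrna, , drop = FALSE]
    if (nrow(pcl) == 0) next
    sponge_edges <- targets[targets$target_class == cl, , drop = FALSE]
    mrna_edges <- targets[targets$target_class == "mRNA", , drop = FALSE]
    for (i in seq_len(nrow(pcl))) {
      s <- pcl$ncrna[i]; g <- pcl$mrna[i]
      shared <- intersect(sponge_edges$mirna[sponge_edges$target == s],
                          mrna_edges$mirna[mrna_edges$target == g])
      for (m in shared) {
        mdir <- "unknown"
        if (!is.null(mirna_de)) {
          hit <- match(m, mirna_de$feature)
          if (!is.na(hit) && mirna_de$passes[hit]) mdir <- mirna_de$direction[hit]
        }
        sdir <- dir_of(cl, s)
        if (strict_mirna) {
          opposite <- (sdir == "up" && mdir == "down") ||
            (sdir == "down" && mdir == "up")
          if (!opposite) next
        }
        n_out <- n_out + 1
        rows[[n_out]] <- data.frame(
          sponge = s, sponge_class = cl, mirna = m, mrna = g,
          r = pcl$r[i], p = pcl$p[i],
          sponge_direction = sdir, mrna_direction = dir_of("mRNA", g),
          mirna_direction = mdir, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_out == 0) return(empty)
  out <- do.call(rbind, rows[seq_len(n_out)])
  out <- unique(out)
  out <- out[order(out$mirna, out$sponge, out$mrna), ]
  rownames(out) <- NULL
  out
}

#' Build the tripartite ceRNA network
#'
#' Union graph of all triplet edges (miRNA-sponge, miRNA-mRNA and the
#' sponge-mRNA coexpression edge), with deduplicated nodes carrying `class`
#' and `direction` attributes and edges carrying a `type` attribute.
#'
#' @param triplets data.frame from [find_triplets()].
#' @return an [igraph::igraph] with graph attribute `summary`, see
#'   [network_summary()].
#' @export
build_network <- function(triplets) {
  if (nrow(triplets) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    igraph::graph_attr(g, "summary") <- list(
      n_triplets = 0L, n_sponges = 0L, n_mirnas = 0L, n_mrnas = 0L)
    return(g)
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$sponge, class = triplets$sponge_class,
               direction = triplets$sponge_direction, stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna, class = "miRNA",
               direction = triplets$mirna_direction, stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna, class = "mRNA",
               direction = triplets$mrna_direction, stringsAsFactors = FALSE)))
  if (anyDuplicated(nodes$id))
    stop("conflicting attributes for a node across triplets", call. = FALSE)
  edges <- unique(rbind(
    data.frame(from = triplets$mirna, to = triplets$sponge,
               type = "mirna_sponge", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna, to = triplets$mrna,
               type = "mirna_mrna", stringsAsFactors = FALSE),
    data.frame(from = triplets$sponge, to = triplets$mrna,
               type = "coexpression", stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::graph_attr(g, "summary") <- list(
    n_triplets = nrow(unique(triplets[, c("sponge", "mirna", "mrna")])),
    n_sponges = length(unique(triplets$sponge)),
    n_mirnas = length(unique(triplets$mirna)),
    n_mrnas = length(unique(triplets$mrna)))
  g
}

#' Node and edge counts of a ceRNA network
#'
#' @param network an igraph from [build_network()].
#' @return list with `n_triplets`, `n_sponges`, `n_mirnas`, `n_mrnas`,
#'   `n_nodes`, `n_edges`.
#' @export
network_summary <- function(network) {
  s <- igraph::graph_attr(network, "summary")
  if (is.null(s)) s <- list(n_triplets = NA_integer_,
                            n_sponges = NA_integer_, n_mirnas = NA_integer_,
                            n_mrnas = NA_integer_)
  c(s, list(n_nodes = as.integer(igraph::vcount(network)),
            n_edges = as.integer(igraph::ecount(network))))
}

#' Export a ceRNA network
#'
#' Writes the network in any of three interchange forms: SIF
#' (`source<TAB>interaction<TAB>target`, one line per edge), GraphML (via
#' [igraph::write_graph()]), and a node/edge TSV pair that round-trips
#' losslessly through [import_network_tsv()].
#'
#' @param network an igraph from [build_network()].
#' @param basename output path prefix; files get suffixes `.sif`,
#'   `.graphml`, `_nodes.tsv`, `_edges.tsv`.
#' @param formats subset of `c("sif", "graphml", "tsv")`.
#' @return named character vector of the files written, invisibly.
#' @export
export_network <- function(network, basename,
                           formats = c("sif", "graphml", "tsv")) {
  unknown <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(unknown) > 0)
    stop("unknown format(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ed <- igraph::as_data_frame(network, what = "edges")
  nd <- igraph::as_data_frame(network, what = "vertices")
  names(nd)[names(nd) == "name"] <- "id"
  paths <- character(0)
  if ("sif" %in% formats) {
    path <- paste0(basename, ".sif")
    writeLines(paste(ed$from, ed$type, ed$to, sep = "\t"), path)
    paths["sif"] <- path
  }
  if ("graphml" %in% formats) {
    path <- paste0(basename, ".graphml")
    igraph::write_graph(network, path, format = "graphml")
    paths["graphml"] <- path
  }
  if ("tsv" %in% formats) {
    npath <- paste0(basename, "_nodes.tsv")
    epath <- paste0(basename, "_edges.tsv")
    write_tsv_file(nd, npath)
    write_tsv_file(ed[, c("from", "to", "type")], epath)
    paths["nodes"] <- npath
    paths["edges"] <- epath
  }
  invisible(paths)
}

#' Re-import a network from its node/edge TSV pair
#'
#' @param nodes_path,edges_path paths written by [export_network()].
#' @return an igraph equal (up to the unrecoverable summary attribute) to
#'   the exported network.
#' @export
import_network_tsv <- function(nodes_path, edges_path) {
  nd <- read_tsv_file(nodes_path, c("id", "class", "direction"))
  ed <- read_tsv_file(edges_path, c("from", "to", "type"))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
}
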