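utils::globalVariables(c("log2fc", "p", "direction"))

#' Volcano plot of a DE table
#'
#' log2 fold change against -log10 p, colored by call direction, with the
#' fold-change and significance thresholds drawn as reference lines.
#'
#' @param de data.frame from [call_de()].
#' @param thresholds a [threshold_config()] (for the reference lines).
#' @return a ggplot object.
#' @export
plot_volcano <- function(de, thresholds = threshold_config()) {
  d <- de[!is.na(de$p), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = log2fc, y = -log10(p),
                                  color = direction)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$lfc_threshold,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(thresholds$p_threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                           null = "grey70")) +
    ggplot2::labs(x = "log2 fold change (A vs H)", y = "-log10 p",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of DE features
#'
#' Row-scaled heatmap (log2 expression) of the passing features of a DE
#' table, samples annotated by group.
#'
#' @param mat expression matrix the DE table was computed from.
#' @param de data.frame from [call_de()].
#' @param meta sample metadata (`sample`, `group`).
#' @param pseudocount added before the log2 transform.
#' @param filename optional file to write (passed to
#'   [pheatmap::pheatmap()]).
#' @return the pheatmap object, invisibly.
#' @export
plot_de_heatmap <- function(mat, de, meta, pseudocount = 0.01,
                            filename = NA) {
  ids <- de$feature[de$passes]
  if (length(ids) < 2) stop("need >= 2 passing features for a heatmap",
                            call. = FALSE)
  m <- log2(mat[ids, , drop = FALSE] + pseudocount)
  ann <- data.frame(group = meta$group[match(colnames(m), meta$sample)],
                    row.names = colnames(m))
  ph <- pheatmap::pheatmap(m, scale = "row", annotation_col = ann,
                           silent = TRUE, filename = filename)
  invisible(ph)
}
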