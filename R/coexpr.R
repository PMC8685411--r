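#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant vector", call. = FALSE)
  cor(x, y)
}

#' Exact two-sided p value of a Pearson correlation
#'
#' Uses the t-transform of the correlation coefficient:
#' `t = |r| * sqrt((n - 2) / (1 - r^2))` follows a t-distribution with
#' `n - 2` degrees of freedom under the null of no correlation, and
#' `p = 2 * P(T >= t)` from the exact t CDF. `|r| = 1` maps to p = 0.
#' Vectorized over `r` and `n`.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param n sample size(s), >= 3.
#' @return two-sided p value(s) in `[0, 1]`.
#' @export
correlation_p <- function(r, n) {
  if (any(n < 3)) stop("insufficient samples: n must be >= 3", call. = FALSE)
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  ifelse(abs(r) == 1, 0, pmin(p, 1))
}

#' Coexpressed DE ncRNA-mRNA pairs
#'
#' Computes the Pearson correlation over all samples between every passing
#' DE ncRNA (lncRNA or circRNA) and every passing DE mRNA, on the
#' log2(x + pseudocount) scale, and keeps pairs with `|r| >= r_threshold`
#' and correlation-test `p < p_threshold`. The correlation sign is kept per
#' pair: strong coexpression in either direction is retained, with positive
#' pairs the ones eligible for ceRNA triplets downstream.
#'
#' @param de_nc,de_mrna DE tables from [call_de()] for the ncRNA class and
#'   for mRNA, computed on the same samples.
#' @param mat_nc,mat_mrna the matching expression matrices.
#' @param r_threshold minimum absolute correlation (default 0.8).
#' @param p_threshold correlation-test significance cutoff (default 0.05).
#' @param pseudocount added before the log2 transform.
#' @return data.frame sorted by p ascending (ties by ncRNA then mRNA id):
#'   `ncrna`, `ncrna_class`, `mrna`, `r`, `p`, `n`, `mrna_log2fc`.
#' @export
coexpression_pairs <- function(de_nc, de_mrna, mat_nc, mat_mrna,
                               r_threshold = 0.8, p_threshold = 0.05,
                               pseudocount = 0.01) {
  if (!identical(colnames(mat_nc), colnames(mat_mrna)))
    stop("design error: matrices must share the same samples in the same order",
         call. = FALSE)
  n <- ncol(mat_nc)
  nc_ids <- de_nc$feature[de_nc$passes]
  m_ids <- de_mrna$feature[de_mrna$passes]
  empty <- data.frame(ncrna = character(0), ncrna_class = character(0),
                      mrna = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0), mrna_log2fc = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(nc_ids) == 0 || length(m_ids) == 0 || r_threshold > 1)
    return(empty)
  R <- cor(t(log2(mat_nc[nc_ids, , drop = FALSE] + pseudocount)),
           t(log2(mat_mrna[m_ids, , drop = FALSE] + pseudocount)))
  P <- matrix(correlation_p(as.vector(R), n), nrow(R), ncol(R))
  keep <- which(abs(R) >= r_threshold & P < p_threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty)
  out <- data.frame(
    ncrna = nc_ids[keep[, 1]],
    ncrna_class = de_nc$class[match(nc_ids[keep[, 1]], de_nc$feature)],
    mrna = m_ids[keep[, 2]],
    r = R[keep], p = P[keep], n = n,
    mrna_log2fc = de_mrna$log2fc[match(m_ids[keep[, 2]], de_mrna$feature)],
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$ncrna, out$mrna), ]
  rownames(out) <- NULL
  out
}
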