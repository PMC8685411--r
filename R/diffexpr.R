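#' Differential-expression thresholds
#'
#' @param lfc_threshold minimum absolute log2 fold change (default 1, i.e.
#'   fold change >= 2 or <= 0.5).
#' @param p_threshold significance cutoff (default 0.05).
#' @param pseudocount added to group means before the log ratio and to
#'   expression values before log2 transformation, guarding zeros.
#' @param use_fdr_for_call if `TRUE`, gate calls on the BH-adjusted q value
#'   instead of the raw p value. q is reported either way.
#' @return list of class `"threshold_config"`.
#' @export
threshold_config <- function(lfc_threshold = 1, p_threshold = 0.05,
                             pseudocount = 0.01, use_fdr_for_call = FALSE) {
  if (lfc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be > 0", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  structure(list(lfc_threshold = lfc_threshold, p_threshold = p_threshold,
                 pseudocount = pseudocount,
                 use_fdr_for_call = isTRUE(use_fdr_for_call)),
            class = "threshold_config")
}

#' Log2 fold change of group means
#'
#' `log2((mean_a + c) / (mean_h + c))`, the A-over-H log ratio with a
#' pseudocount guard. Vectorized.
#'
#' @param mean_a,mean_h nonnegative group means of normalized expression.
#' @param c pseudocount (>= 0).
#' @return log2 fold change(s).
#' @export
log2_fold_change <- function(mean_a, mean_h, c = 0.01) {
  if (any(mean_a < 0) || any(mean_h < 0) || c < 0)
    stop("means and pseudocount must be nonnegative", call. = FALSE)
  if (any(mean_a + c == 0) || any(mean_h + c == 0))
    stop("undefined ratio: zero mean with zero pseudocount", call. = FALSE)
  log2((mean_a + c) / (mean_h + c))
}

#' Paired t-test
#'
#' Two-sided paired t-test on `x - y` with `n - 1` degrees of freedom.
#' Pairs with zero difference variance carry no information about the
#' variance and are rejected as degenerate rather than reported with p = 0.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of equal length >= 2", call. = FALSE)
  d <- x - y
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0)
    stop("degenerate test: zero variance of paired differences", call. = FALSE)
  fit <- t.test(x, y, paired = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value,
       df = unname(fit$parameter))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the tested (non-missing) hypotheses.
#' Missing values are passed through unadjusted and do not count toward the
#' number of tests.
#'
#' @param pvals numeric vector of p values in `[0, 1]`, `NA` allowed.
#' @return adjusted values, same length and order, `NA` where input was
#'   `NA`.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvals))
  out[ok] <- p.adjust(pvals[ok], method = "BH")
  out
}

#' Call differentially expressed features
#'
#' Per-feature paired t-test between groups A and H on log2-transformed
#' expression (`log2(x + pseudocount)`), BH adjustment across the tested
#' features of the matrix, and threshold calls: a feature passes iff
#' `|log2FC| >= lfc_threshold` and the gating p value (raw p, or q when
#' `use_fdr_for_call`) is below `p_threshold`. The log2 fold change is
#' computed from the raw group means, not the log-scale means, since the
#' input is already-normalized expression.
#'
#' Features whose paired differences have zero variance are flagged
#' `degenerate`, get missing t/p/q, and never pass.
#'
#' @param mat numeric matrix, features x samples, rownames = feature ids,
#'   colnames matching `meta$sample`.
#' @param meta data.frame with columns `sample`, `group` (values "A"/"H")
#'   and optionally `pair`; when `pair` is present samples are matched on
#'   it, otherwise by within-group order.
#' @param rna_class label recorded in the output (one of mRNA, lncRNA,
#'   circRNA, miRNA).
#' @param thresholds a [threshold_config()].
#' @return data.frame with one row per feature: `feature`, `class`,
#'   `mean_A`, `mean_H`, `log2fc`, `t`, `p`, `q`, `direction`
#'   ("up"/"down"/"null"), `passes`, `degenerate`.
#' @export
call_de <- function(mat, meta, rna_class = "mRNA",
                    thresholds = threshold_config()) {
  if (anyDuplicated(rownames(mat)))
    stop("duplicate feature ids", call. = FALSE)
  if (!all(c("A", "H") %in% meta$group))
    stop("design error: both groups A and H must be present", call. = FALSE)
  meta <- meta[match(colnames(mat), meta$sample), ]
  if (anyNA(meta$sample))
    stop("design error: matrix columns missing from metadata", call. = FALSE)
  a_meta <- meta[meta$group == "A", ]
  h_meta <- meta[meta$group == "H", ]
  if ("pair" %in% names(meta)) {
    if (!setequal(a_meta$pair, h_meta$pair) ||
        anyDuplicated(a_meta$pair) || anyDuplicated(h_meta$pair))
      stop("design error: pair ids must be a bijection between groups",
           call. = FALSE)
    h_meta <- h_meta[match(a_meta$pair, h_meta$pair), ]
  } else if (nrow(a_meta) != nrow(h_meta)) {
    stop("design error: unpaired groups of unequal size; supply pair ids",
         call. = FALSE)
  }
  A <- mat[, a_meta$sample, drop = FALSE]
  H <- mat[, h_meta$sample, drop = FALSE]
  npair <- ncol(A)
  if (npair < 2) stop("design error: need >= 2 pairs", call. = FALSE)

  c0 <- thresholds$pseudocount
  mean_A <- rowMeans(A)
  mean_H <- rowMeans(H)
  l2fc <- log2_fold_change(mean_A, mean_H, c0)

  # vectorized paired t on the log2 scale
  D <- log2(A + c0) - log2(H + c0)
  dbar <- rowMeans(D)
  dvar <- apply(D, 1, var)
  degen <- dvar <= .Machine$double.eps * pmax(1, dbar^2)
  tstat <- ifelse(degen, NA_real_, dbar / sqrt(dvar / npair))
  p <- 2 * pt(abs(tstat), df = npair - 1, lower.tail = FALSE)
  q <- bh_adjust(p)

  gate <- if (thresholds$use_fdr_for_call) q else p
  passes <- !is.na(gate) & abs(l2fc) >= thresholds$lfc_threshold &
    gate < thresholds$p_threshold
  direction <- ifelse(passes, ifelse(l2fc > 0, "up", "down"), "null")
  data.frame(
    feature = rownames(mat), class = rna_class,
    mean_A = mean_A, mean_H = mean_H, log2fc = l2fc,
    t = tstat, p = p, q = q, direction = direction,
    passes = passes, degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Tally a DE table
#'
#' @param de a data.frame from [call_de()].
#' @return data.frame with `total`, `up`, `down` counts of passing features
#'   (`total = up + down` by construction).
#' @export
de_summary <- function(de) {
  data.frame(total = sum(de$passes),
             up = sum(de$direction == "up"),
             down = sum(de$direction == "down"))
}
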