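#' Relative expression by the 2^-dCt method
#'
#' Averages technical replicates on the Ct scale, forms
#' `dCt = Ct(target) - Ct(reference)` per sample and returns
#' `2^-dCt`, the expression of the target relative to the reference
#' (housekeeping) gene. `log2` of the returned value equals `-dCt` exactly.
#'
#' @param ct_table data.frame with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct` (Ct in PCR cycles, > 0).
#' @param target assayed gene id.
#' @param reference reference gene id; must be measured in every sample
#'   that carries the target.
#' @return data.frame with one row per sample: `sample`, `group`,
#'   `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct_table, target, reference = "ACTB") {
  tt <- ct_table[ct_table$gene == target, , drop = FALSE]
  rt <- ct_table[ct_table$gene == reference, , drop = FALSE]
  if (nrow(tt) == 0) stop("target gene not in table: ", target, call. = FALSE)
  ct_mean <- function(d) {
    ag <- stats::aggregate(ct ~ sample + group, data = d, FUN = mean)
    setNames(ag$ct, ag$sample)
  }
  ct_t <- ct_mean(tt)
  if (nrow(rt) == 0)
    stop("missing reference gene for sample(s): ",
         paste(sort(unique(tt$sample)), collapse = ", "), call. = FALSE)
  ct_r <- ct_mean(rt)
  missing_ref <- setdiff(names(ct_t), names(ct_r))
  if (length(missing_ref) > 0)
    stop("missing reference gene for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  groups <- tt$group[match(names(ct_t), tt$sample)]
  dct <- ct_t - ct_r[names(ct_t)]
  out <- data.frame(sample = names(ct_t), group = groups,
                    delta_ct = unname(dct), rel_expr = unname(2^-dct),
                    stringsAsFactors = FALSE)
  out[order(out$sample), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Two-group comparison of relative expression
#'
#' Two-sided Student's t-test (equal variances by default; set
#' `var_equal = FALSE` for Welch) between the A and H groups, with per-group
#' mean and SD summaries. Two identical groups give t = 0, p = 1; groups
#' that are both constant carry no variance information and raise a
#' degenerate-test error.
#'
#' @param values_a,values_h numeric vectors (e.g. per-sample 2^-dCt),
#'   length >= 2 each.
#' @param var_equal pool variances (classical Student test) or not (Welch).
#' @return list with `t`, `p`, `mean_a`, `sd_a`, `mean_h`, `sd_h`.
#' @export
group_compare <- function(values_a, values_h, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_h) < 2)
    stop("need >= 2 values per group", call. = FALSE)
  if (var(values_a) == 0 && var(values_h) == 0) {
    if (mean(values_a) == mean(values_h)) {
      return(list(t = 0, p = 1, mean_a = mean(values_a), sd_a = 0,
                  mean_h = mean(values_h), sd_h = 0))
    }
    stop("degenerate test: zero variance in both groups", call. = FALSE)
  }
  fit <- t.test(values_a, values_h, var.equal = var_equal)
  list(t = unname(fit$statistic), p = fit$p.value,
       mean_a = mean(values_a), sd_a = sd(values_a),
       mean_h = mean(values_h), sd_h = sd(values_h))
}

#' Per-gene qPCR validation analysis
#'
#' Runs [relative_expression()] and [group_compare()] for each assayed gene
#' (all genes in the table except the reference, unless `targets` is
#' given).
#'
#' @param ct_table Ct table as in [relative_expression()].
#' @param targets genes to analyze; defaults to all non-reference genes.
#' @param reference reference gene id.
#' @param var_equal see [group_compare()].
#' @return data.frame with one row per gene: `gene`, `mean_a`, `sd_a`,
#'   `mean_h`, `sd_h`, `t`, `p`, `direction` ("up"/"down" by sign of the
#'   A-vs-H mean difference).
#' @export
qpcr_analysis <- function(ct_table, targets = NULL, reference = "ACTB",
                          var_equal = TRUE) {
  if (is.null(targets)) targets <- setdiff(unique(ct_table$gene), reference)
  rows <- lapply(targets, function(g) {
    rel <- relative_expression(ct_table, g, reference)
    cmp <- group_compare(rel$rel_expr[rel$group == "A"],
                         rel$rel_expr[rel$group == "H"],
                         var_equal = var_equal)
    data.frame(gene = g, mean_a = cmp$mean_a, sd_a = cmp$sd_a,
               mean_h = cmp$mean_h, sd_h = cmp$sd_h,
               t = cmp$t, p = cmp$p,
               direction = if (cmp$mean_a >= cmp$mean_h) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
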