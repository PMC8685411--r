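#' Gene-set collection
#'
#' A light container for GO/KEGG-style annotation: parallel vectors of term
#' id, human-readable name and category, plus a list of member gene ids per
#' term. Categories follow the GO/KEGG split: biological process (BP),
#' cellular component (CC), molecular function (MF), or pathway.
#'
#' @param id unique term ids.
#' @param name term names.
#' @param category per-term category in `c("BP","CC","MF","pathway")`.
#' @param members list of non-empty character vectors of gene ids.
#' @return list of class `"gene_sets"`.
#' @export
gene_sets <- function(id, name = id, category = rep("BP", length(id)),
                      members) {
  if (anyDuplicated(id)) stop("term ids must be unique", call. = FALSE)
  if (length(name) != length(id) || length(category) != length(id) ||
      length(members) != length(id))
    stop("id, name, category and members must be parallel", call. = FALSE)
  if (any(lengths(members) == 0))
    stop("member lists must be non-empty", call. = FALSE)
  names(members) <- id
  structure(list(id = as.character(id), name = as.character(name),
                 category = as.character(category), members = members),
            class = "gene_sets")
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes when drawing `n` genes from a universe of
#' `N` containing `K` annotated ones. This is the over-representation
#' (one-sided Fisher) p value. Vectorized.
#'
#' @param k observed overlap.
#' @param K term size within the universe.
#' @param n size of the drawn (DE) set.
#' @param N universe size.
#' @return p value(s) in `[0, 1]`.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent counts: need 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis
#'
#' Tests every term of a collection for enrichment of a DE gene set within
#' a universe, with BH adjustment across the tested terms. Term membership
#' is intersected with the universe first; terms with no member in the
#' universe are dropped.
#'
#' @param de_set character vector of DE gene ids, must be a subset of
#'   `universe`.
#' @param universe character vector of all testable gene ids (conventionally
#'   the genes present in the expression matrix and the annotation).
#' @param collection a [gene_sets()] object.
#' @return data.frame sorted by p ascending (ties by term id): `term`,
#'   `name`, `category`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
ora <- function(de_set, universe, collection) {
  stopifnot(inherits(collection, "gene_sets"))
  de_set <- unique(de_set)
  universe <- unique(universe)
  if (!all(de_set %in% universe))
    stop("validation error: de_set must be a subset of the universe",
         call. = FALSE)
  N <- length(universe)
  n <- length(de_set)
  Kv <- vapply(collection$members,
               function(m) length(intersect(m, universe)), integer(1))
  keep <- Kv > 0
  kv <- vapply(collection$members[keep],
               function(m) length(intersect(m, de_set)), integer(1))
  p <- hypergeometric_tail(kv, Kv[keep], n, N)
  out <- data.frame(term = collection$id[keep], name = collection$name[keep],
                    category = collection$category[keep],
                    k = kv, K = Kv[keep], n = n, N = N,
                    p = p, q = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Top-ranked enrichment records
#'
#' @param records data.frame from [ora()].
#' @param n_top number of leading terms to keep (default 30, the
#'   conventional plotting depth).
#' @return first `min(n_top, nrow)` rows.
#' @export
top_terms <- function(records, n_top = 30) {
  head(records, n_top)
}
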