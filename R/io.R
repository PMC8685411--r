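# Tabular readers/writers. All tables are plain TSV with a header row, no
# quoting, "." decimal; writers are deterministic so reruns are
# byte-identical.

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv_file <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(nf) == 0) stop("parse error in ", path, ": empty file", call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad) > 0)
    stop("parse error in ", path, ": line ", bad[1], " has ", nf[bad[1]],
         " fields, expected ", nf[1], call. = FALSE)
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(df))
    if (length(miss) > 0)
      stop("parse error in ", path, ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read an expression matrix as TSV
#'
#' Layout: a `feature` id column followed by one column per sample.
#'
#' @param mat numeric matrix, features x samples, with dimnames.
#' @param path file path.
#' @return `write_expression_tsv` the path invisibly; `read_expression_tsv`
#'   the matrix.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_file(path, "feature")
  if (anyDuplicated(df$feature))
    stop("parse error in ", path, ": duplicate feature ids", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "feature"), drop = FALSE])
  if (!is.numeric(m))
    stop("parse error in ", path, ": non-numeric expression values",
         call. = FALSE)
  rownames(m) <- df$feature
  m
}

#' Write / read sample metadata as TSV
#'
#' Columns: `sample`, `group` and optionally `pair`.
#'
#' @param meta data.frame.
#' @param path file path.
#' @export
write_metadata_tsv <- function(meta, path) write_tsv_file(meta, path)

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) read_tsv_file(path, c("sample", "group"))

#' Write / read a miRNA-target map as TSV
#'
#' Columns: `mirna`, `target`, `target_class`.
#'
#' @param targets data.frame of edges.
#' @param path file path.
#' @export
write_target_map_tsv <- function(targets, path) write_tsv_file(targets, path)

#' @rdname write_target_map_tsv
#' @export
read_target_map_tsv <- function(path)
  read_tsv_file(path, c("mirna", "target", "target_class"))

#' Write / read a qPCR Ct table as TSV
#'
#' Columns: `sample`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param ct_table data.frame.
#' @param path file path.
#' @export
write_ct_tsv <- function(ct_table, path) write_tsv_file(ct_table, path)

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path)
  read_tsv_file(path, c("sample", "group", "gene", "replicate", "ct"))

#' Write / read a DE table as TSV
#'
#' @param de data.frame from [call_de()].
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) write_tsv_file(de, path)

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path)
  read_tsv_file(path, c("feature", "class", "log2fc", "p", "q", "direction",
                        "passes"))

#' Write / read gene sets in GMT format
#'
#' One term per line: `id<TAB>description<TAB>gene1<TAB>gene2...`. The term
#' category (BP/CC/MF/pathway) is carried in the description field as
#' `category|name`, keeping the round trip lossless.
#'
#' @param gs a [gene_sets()] object.
#' @param path file path.
#' @export
write_gmt <- function(gs, path) {
  stopifnot(inherits(gs, "gene_sets"))
  lines <- vapply(seq_along(gs$id), function(i) {
    paste(c(gs$id[i], paste0(gs$category[i], "|", gs$name[i]),
            gs$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop("parse error in ", path, ": line ", short[1],
         " has fewer than 3 fields", call. = FALSE)
  id <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  has_cat <- grepl("^(BP|CC|MF|pathway)\\|", desc)
  category <- ifelse(has_cat, sub("\\|.*$", "", desc), "BP")
  name <- ifelse(has_cat, sub("^[^|]*\\|", "", desc), desc)
  members <- lapply(fields, function(f) f[-(1:2)])
  gene_sets(id, name, category, members)
}
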