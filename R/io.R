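#' Read / write expression matrices and arm maps as TSV
#'
#' The expression table has genes in rows (`gene_id` first column) and
#' samples in columns; the arm map is a two-column TSV `sample_id`, `arm`.
#'
#' @param expr_path Expression TSV path.
#' @param arm_path Arm-map TSV path.
#' @return `read_expression_tsv()` returns an [expression_matrix()].
#' @export
read_expression_tsv <- function(expr_path, arm_path) {
  df <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") {
    stopf("'%s' must have 'gene_id' as its first column", expr_path)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  arm_df <- read.delim(arm_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "arm") %in% names(arm_df))) {
    stopf("'%s' must have columns sample_id, arm", arm_path)
  }
  expression_matrix(values, setNames(arm_df$arm, arm_df$sample_id))
}

#' @param expr An [expression_matrix()] to write.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expr, expr_path, arm_path) {
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  arm_df <- data.frame(sample_id = names(expr$arms), arm = unname(expr$arms),
                       stringsAsFactors = FALSE)
  write.table(arm_df, arm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, arm_path))
}

#' Read a GEO series-matrix text export
#'
#' Parses the series-matrix dialect: `!`-prefixed metadata lines, then a
#' table between `!series_matrix_table_begin` and `!series_matrix_table_end`
#' with `ID_REF` and one column per sample (GSM accession). Arm labels are
#' supplied by the caller as a named vector, since series metadata rarely
#' encodes the experimental arms unambiguously. Values are taken as already
#' log2 scale; samples with no arm assignment are dropped with a message.
#'
#' @param path Series-matrix file (uncompressed text).
#' @param arm_map Named character vector: sample accession to arm label.
#' @return An [expression_matrix()].
#' @export
read_geo_series_matrix <- function(path, arm_map) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stopf("'%s' has no series-matrix table block", path)
  }
  tab <- lines[(begin + 1L):(end - 1L)]
  con <- textConnection(tab)
  on.exit(close(con))
  df <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- gsub('^"|"$', "", names(df))
  if (!names(df)[1] %in% c("ID_REF", "\"ID_REF\"")) {
    stopf("series-matrix table must start with an ID_REF column")
  }
  ids <- gsub('^"|"$', "", as.character(df[[1]]))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  known <- intersect(colnames(values), names(arm_map))
  dropped <- setdiff(colnames(values), known)
  if (length(dropped)) {
    message(sprintf("dropping %d samples without an arm assignment: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (!length(known)) stopf("no sample in '%s' matches the arm map", path)
  expression_matrix(values[, known, drop = FALSE], arm_map[known])
}
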