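#' Construct a pathway collection
#'
#' Named gene sets over a gene universe. Pathway members outside the universe
#' are dropped (with a message reporting how many); pathways left empty after
#' the restriction are removed with a warning.
#'
#' @param pathways Named list of character vectors (gene ids per pathway id).
#' @param universe Character vector, the annotated gene universe.
#' @param names Optional named character vector of human-readable pathway
#'   names; defaults to the ids.
#' @return A `pathway_collection` object.
#' @export
pathway_collection <- function(pathways, universe, names = NULL) {
  if (!length(pathways) || is.null(base::names(pathways))) {
    stopf("'pathways' must be a non-empty named list")
  }
  universe <- unique(as.character(universe))
  restricted <- lapply(pathways, function(g) unique(g[g %in% universe]))
  dropped <- sum(lengths(pathways)) - sum(lengths(restricted))
  if (dropped > 0) {
    message(sprintf("dropped %d pathway genes outside the universe", dropped))
  }
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warnf("removed %d pathways left empty after universe restriction", sum(empty))
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) stopf("no pathways remain after restriction")
  if (is.null(names)) names <- setNames(base::names(restricted),
                                        base::names(restricted))
  structure(
    list(pathways = restricted, names = names, universe = universe),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways over %d genes (sizes %d-%d)\n",
              length(x$pathways), length(x$universe),
              min(lengths(x$pathways)), max(lengths(x$pathways))))
  invisible(x)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` query genes inside a pathway of size
#' `K` when `n` genes are drawn without replacement from a universe of `N`.
#' This is the classical one-sided over-representation test; `k = 0` gives
#' p = 1 by construction.
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Pathway size.
#' @param N Universe size.
#' @return The p-value P(X >= k).
#' @export
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
hypergeom_pvalue <- function(k, n, K, N) {
  ok <- is_count(N) && k >= 0 && k == floor(k) &&
    is_count(n + 1) && is_count(K + 1) &&
    n <= N && K <= N && k <= min(n, K)
  if (!ok) {
    stopf("inconsistent counts: need 0 <= k <= min(n, K) <= N (got k=%s, n=%s, K=%s, N=%s)",
          format(k), format(n), format(K), format(N))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pathway over-representation analysis
#'
#' Restricts the query to the collection's universe, scores every pathway
#' with the upper-tail hypergeometric test, and controls the FDR across
#' pathways with Benjamini-Hochberg. Rows are ordered by p-value, ties broken
#' by pathway id.
#'
#' @param query Character vector of gene ids.
#' @param coll A [pathway_collection()].
#' @return An `enrichment_result` data frame with columns `pathway_id`,
#'   `name`, `overlap`, `pathway_size`, `query_size`, `universe_size`,
#'   `pvalue`, `qvalue`, `overlap_genes` (semicolon-joined).
#' @export
enrich_pathways <- function(query, coll) {
  if (!inherits(coll, "pathway_collection")) {
    stopf("'coll' must be a pathway_collection")
  }
  query <- unique(as.character(query))
  query <- query[query %in% coll$universe]
  if (!length(query)) {
    stopf("query has no genes in the pathway universe")
  }
  N <- length(coll$universe)
  n <- length(query)
  rows <- lapply(names(coll$pathways), function(pid) {
    genes <- coll$pathways[[pid]]
    ov <- intersect(query, genes)
    data.frame(
      pathway_id = pid,
      name = unname(coll$names[pid]),
      overlap = length(ov),
      pathway_size = length(genes),
      query_size = n,
      universe_size = N,
      pvalue = hypergeom_pvalue(length(ov), n, length(genes), N),
      overlap_genes = paste(sort(ov), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$qvalue <- p.adjust(res$pvalue, method = "BH")
  res <- res[order(res$pvalue, res$pathway_id), ]
  rownames(res) <- NULL
  res <- res[c("pathway_id", "name", "overlap", "pathway_size", "query_size",
               "universe_size", "pvalue", "qvalue", "overlap_genes")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Read / write gene sets in GMT format
#'
#' One pathway per line: id, description, then tab-separated member genes.
#'
#' @param path File path.
#' @param universe Universe passed to [pathway_collection()]; defaults to the
#'   union of all member genes.
#' @return `read_gmt()` returns a [pathway_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stopf("'%s': %d GMT lines have fewer than 3 fields", path, sum(bad))
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate pathway ids in '%s'", path)
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  pathway_collection(sets, universe, names = setNames(descs, ids))
}

#' @param coll A [pathway_collection()] to write.
#' @rdname read_gmt
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$pathways), function(pid) {
    paste(c(pid, unname(coll$names[pid]), coll$pathways[[pid]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an enrichment table as TSV
#'
#' @param res An `enrichment_result`.
#' @param path File path.
#' @export
write_enrichment_tsv <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
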