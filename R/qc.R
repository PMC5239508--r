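#' Hierarchical clustering of samples over a gene subset
#'
#' Agglomerative (average-linkage) clustering of samples on Euclidean
#' distance over the chosen genes, the standard QC view that disease and
#' control arms should separate when clustered on the dysregulated genes.
#' Samples are ordered lexicographically before clustering so that ties in
#' the distance matrix are broken by sample id, making the leaf order
#' deterministic.
#'
#' @param expr An [expression_matrix()].
#' @param gene_subset Non-empty character vector of gene ids to cluster on.
#' @param method Linkage passed to [stats::hclust()].
#' @return The `hclust` object (leaf order in `$order`, heights in
#'   `$height`).
#' @export
cluster_samples <- function(expr, gene_subset, method = "average") {
  gene_subset <- unique(as.character(gene_subset))
  if (!length(gene_subset)) stopf("empty gene subset")
  missing <- setdiff(gene_subset, gene_ids(expr))
  if (length(missing)) {
    stopf("genes not in the expression matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  m <- t(expr$values[gene_subset, , drop = FALSE])
  m <- m[order(rownames(m)), , drop = FALSE]
  hclust(dist(m, method = "euclidean"), method = method)
}

#' Cut a sample dendrogram and report cluster purity by arm
#'
#' @param hc An `hclust` from [cluster_samples()].
#' @param expr The matching [expression_matrix()].
#' @param k Number of clusters.
#' @return Data frame with `sample_id`, `arm`, `cluster`.
#' @export
cut_sample_clusters <- function(hc, expr, k = 2) {
  cl <- stats::cutree(hc, k = k)
  data.frame(sample_id = names(cl),
             arm = unname(expr$arms[names(cl)]),
             cluster = unname(cl),
             stringsAsFactors = FALSE)
}

#' Principal component analysis of samples
#'
#' SVD of the gene-centered matrix (samples as observations, no scaling).
#' With a constant matrix there is nothing to project: a zero-variance
#' warning is raised and all scores are zero.
#'
#' @param expr An [expression_matrix()].
#' @param gene_subset Optional gene ids to restrict to (default: all genes).
#' @param n_components Number of components to report (capped by the rank).
#' @return List with `scores` (samples x components) and `var_explained`
#'   (fractions in `[0, 1]`, non-increasing, summing to at most 1).
#' @export
pca_samples <- function(expr, gene_subset = NULL, n_components = 2) {
  if (ncol(expr$values) < 2L) stopf("PCA needs at least 2 samples")
  v <- expr$values
  if (!is.null(gene_subset)) {
    gene_subset <- unique(as.character(gene_subset))
    missing <- setdiff(gene_subset, gene_ids(expr))
    if (length(missing)) {
      stopf("genes not in the expression matrix: %s",
            paste(head(missing, 5), collapse = ", "))
    }
    v <- v[gene_subset, , drop = FALSE]
  }
  centered <- t(v - rowMeans(v))
  total_var <- sum(centered^2)
  k <- min(n_components, ncol(centered), nrow(centered) - 1L)
  if (total_var == 0) {
    warnf("constant expression matrix: zero variance, all scores 0")
    scores <- matrix(0, nrow(centered), max(k, 1L),
                     dimnames = list(rownames(centered),
                                     paste0("PC", seq_len(max(k, 1L)))))
    return(list(scores = scores,
                var_explained = rep(0, max(k, 1L))))
  }
  pc <- prcomp(centered, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  )
}
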