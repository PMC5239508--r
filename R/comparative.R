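#' Classify treatment reversal of disease dysregulation
#'
#' Crosses the disease contrast (model vs control) with the treatment
#' contrast (treated vs model) gene by gene:
#' \describe{
#'   \item{reversed}{dysregulated in the model and moved strictly in the
#'     opposite direction by treatment (down in the model, up under
#'     treatment, or the mirror image);}
#'   \item{not_reversed}{dysregulated in the model but not
#'     counter-directional under treatment (unchanged, or pushed further the
#'     same way);}
#'   \item{unaffected}{not dysregulated in the model, whatever the treatment
#'     does.}
#' }
#' The three categories partition the gene universe.
#'
#' @param model_degs Screened `deg_table` for model vs control.
#' @param treat_degs Screened `deg_table` for treatment vs model, over the
#'   same gene universe.
#' @return A `reversal_table` data frame: `gene_id`, `model_direction`,
#'   `treat_direction`, `category`.
#' @export
classify_reversal <- function(model_degs, treat_degs) {
  for (tb in list(model_degs, treat_degs)) {
    if (all(is.na(tb$direction))) {
      stopf("directions are unset; run screen_degs() on both tables first")
    }
  }
  missing <- c(setdiff(model_degs$gene_id, treat_degs$gene_id),
               setdiff(treat_degs$gene_id, model_degs$gene_id))
  if (length(missing)) {
    stopf("gene universes differ; ids present on one side only: %s",
          paste(head(sort(unique(missing)), 10), collapse = ", "))
  }
  treat <- treat_degs[match(model_degs$gene_id, treat_degs$gene_id), ]
  md <- model_degs$direction
  td <- treat$direction
  category <- ifelse(md == "ns", "unaffected",
              ifelse((md == "up" & td == "down") |
                     (md == "down" & td == "up"), "reversed", "not_reversed"))
  res <- data.frame(gene_id = model_degs$gene_id,
                    model_direction = md,
                    treat_direction = td,
                    category = category,
                    stringsAsFactors = FALSE)
  class(res) <- c("reversal_table", "data.frame")
  res
}

#' Core genes regulated by a deleted herb pair
#'
#' Genes dysregulated in \emph{both} herb-deletion arms relative to the full
#' formula: removing either herb perturbs their response, so they are
#' attributed to the removed pair. The operation is the intersection of the
#' two dysregulated (up or down) sets and is symmetric in its arguments.
#'
#' @param minus_a_degs,minus_b_degs Screened `deg_table`s for the two
#'   deleted-herb-arm vs full-formula contrasts.
#' @return Sorted character vector of gene ids.
#' @export
herb_pair_core_genes <- function(minus_a_degs, minus_b_degs) {
  sort(intersect(deg_genes(minus_a_degs), deg_genes(minus_b_degs)))
}

#' Merge known disease-gene lists with source provenance
#'
#' Unions gene lists from multiple curated sources, tagging every gene with
#' the sources that carry it. Gene ids are taken as given (case-normalise
#' upstream if needed); output order is deterministic (sorted).
#'
#' @param sources Named list of character vectors: source label to gene ids.
#' @return A `known_gene_set`: list with `gene_ids` (sorted, unique) and
#'   `source_of` (named list: gene id to its source labels).
#' @export
#' @examples
#' merge_known_genes(list(A = c("TPO", "THRA"), B = c("TPO", "TG")))
merge_known_genes <- function(sources) {
  if (!length(sources) || is.null(names(sources)) || !all(nzchar(names(sources)))) {
    stopf("'sources' must be a non-empty list with source labels as names")
  }
  sources <- lapply(sources, function(g) unique(as.character(g)))
  genes <- sort(unique(unlist(sources)))
  if (!length(genes)) stopf("all sources are empty")
  source_of <- lapply(setNames(genes, genes), function(g) {
    names(sources)[vapply(sources, function(s) g %in% s, logical(1))]
  })
  structure(list(gene_ids = genes, source_of = source_of),
            class = "known_gene_set")
}

#' @export
print.known_gene_set <- function(x, ...) {
  cat(sprintf("known_gene_set: %d genes from %d sources\n",
              length(x$gene_ids),
              length(unique(unlist(x$source_of)))))
  multi <- names(x$source_of)[lengths(x$source_of) > 1]
  if (length(multi)) {
    cat("  multi-source:", paste(multi, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a plain-text gene list
#'
#' One gene id per line; an optional `# label` header line names the source
#' (default: the file name without extension).
#'
#' @param path File path.
#' @return Character vector of gene ids with a `label` attribute.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  label <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) && startsWith(lines[1], "#")) {
    label <- trimws(sub("^#+", "", lines[1]))
    lines <- lines[-1]
  }
  structure(lines, label = label)
}

#' Write a reversal table or gene list as text
#'
#' @param x A `reversal_table` (written as TSV) or character vector (one id
#'   per line).
#' @param path File path.
#' @export
write_reversal_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
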