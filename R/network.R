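#' Construct a scored gene interaction network
#'
#' A simple undirected graph over gene ids with a positive confidence score
#' per edge (STRING-style "combined score", treated as an opaque positive
#' number). Self-loops and duplicate (unordered) edges are rejected.
#'
#' @param edges Data frame with columns `from`, `to`, `combined_score`.
#' @param nodes Optional character vector of node ids; defaults to the edge
#'   endpoints. Isolated nodes are allowed.
#' @param provenance Optional data frame of node annotations (kept as-is,
#'   subset on [induce_subnetwork()]).
#' @return A `gene_network` object.
#' @export
gene_network <- function(edges, nodes = NULL, provenance = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        combined_score = numeric(),
                        stringsAsFactors = FALSE)
  }
  req <- c("from", "to", "combined_score")
  if (!all(req %in% names(edges))) {
    stopf("edge table needs columns: %s", paste(req, collapse = ", "))
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(!is.finite(edges$combined_score)) || any(edges$combined_score <= 0)) {
    stopf("edge scores must be positive and finite")
  }
  if (any(edges$from == edges$to)) stopf("self-loops are not allowed")
  cp <- canonical_pair(edges$from, edges$to)
  key <- paste(cp$from, cp$to, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate edges are not allowed")
  edges$from <- cp$from
  edges$to <- cp$to
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges[req], provenance = provenance),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (!is.null(x$provenance)) {
    cat(sprintf("  provenance tags for %d nodes\n", nrow(x$provenance)))
  }
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)

n_edges <- function(net) nrow(net$edges)

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Build a network from candidate genes and a scored edge table
#'
#' Restricts the edge table to pairs with both endpoints among the candidate
#' genes, then applies the median-score rule: the median combined score of
#' the restricted edges becomes the confidence threshold and only edges at or
#' above it are kept (ties at the median survive, which keeps the rule
#' deterministic). Nodes of the result are the endpoints of the kept edges.
#'
#' @param candidate_genes Character vector of gene ids.
#' @param edges Scored edge table (`from`, `to`, `combined_score`).
#' @return A `gene_network`; its `score_threshold` attribute records the
#'   median used. An empty restriction yields an empty network with a
#'   warning.
#' @export
#' @examples
#' e <- data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "c", "d"),
#'                 combined_score = c(1, 2, 3, 4))
#' net <- build_network(c("a", "b", "c", "d"), e)
#' attr(net, "score_threshold")  # 2.5: the score-1 and score-2 edges drop
build_network <- function(candidate_genes, edges) {
  if (any(edges$combined_score <= 0)) stopf("edge scores must be positive")
  keep <- edges$from %in% candidate_genes & edges$to %in% candidate_genes
  restricted <- edges[keep, , drop = FALSE]
  if (nrow(restricted) == 0L) {
    warnf("no interactions among the %d candidate genes; returning an empty network",
          length(unique(candidate_genes)))
    net <- gene_network(NULL)
    attr(net, "score_threshold") <- NA_real_
    return(net)
  }
  thr <- hn_median(restricted$combined_score)
  net <- gene_network(restricted[restricted$combined_score >= thr, , drop = FALSE])
  attr(net, "score_threshold") <- thr
  net
}

#' Induce a subnetwork on a node subset
#'
#' Keeps edges whose endpoints both lie in `node_subset`, with their scores.
#' Ids absent from the network are dropped with a warning. Provenance
#' annotations, when present, are subset alongside.
#'
#' @param net A `gene_network`.
#' @param node_subset Character vector of node ids.
#' @return A `gene_network` on `node_subset` (including now-isolated nodes).
#' @export
induce_subnetwork <- function(net, node_subset) {
  node_subset <- unique(as.character(node_subset))
  extra <- setdiff(node_subset, net$nodes)
  if (length(extra)) {
    warnf("%d ids not in the network were dropped: %s", length(extra),
          paste(head(extra, 5), collapse = ", "))
    node_subset <- setdiff(node_subset, extra)
  }
  keep <- net$edges$from %in% node_subset & net$edges$to %in% node_subset
  prov <- net$provenance
  if (!is.null(prov)) prov <- prov[prov$gene_id %in% node_subset, , drop = FALSE]
  gene_network(net$edges[keep, , drop = FALSE], nodes = node_subset,
               provenance = prov)
}

#' Assemble the disease-gene / drug-regulating-gene candidate network
#'
#' Takes the four gene sets whose interplay the candidate-target analysis
#' probes — topological hubs of the disease network, known disease genes,
#' treatment-regulating genes, and putative compound targets — tags every
#' gene of the union with its provenance, and filters the scored edge table
#' over that universe with the median-score rule of [build_network()].
#'
#' @param hub_disease_genes,known_genes,drug_regulating_genes,putative_targets
#'   Character vectors (may overlap; at least one must be non-empty).
#' @param edges Scored edge table.
#' @return A `gene_network` whose `provenance` field is a data frame with one
#'   row per union gene and one logical column per source set.
#' @export
assemble_candidate_network <- function(hub_disease_genes, known_genes,
                                       drug_regulating_genes, putative_targets,
                                       edges) {
  universe <- sort(unique(c(hub_disease_genes, known_genes,
                            drug_regulating_genes, putative_targets)))
  if (!length(universe)) stopf("all four gene sets are empty")
  prov <- data.frame(
    gene_id = universe,
    hub_disease = universe %in% hub_disease_genes,
    known = universe %in% known_genes,
    drug_regulating = universe %in% drug_regulating_genes,
    putative_target = universe %in% putative_targets,
    stringsAsFactors = FALSE
  )
  net <- build_network(universe, edges)
  net$provenance <- prov[prov$gene_id %in% net$nodes, , drop = FALSE]
  rownames(net$provenance) <- NULL
  net
}

#' Read / write scored edge tables
#'
#' Tab-separated with header `from`, `to`, `combined_score` (`gene_a` /
#' `gene_b` accepted on read).
#'
#' @param path File path.
#' @return `read_edge_tsv()` returns the edge data frame.
#' @export
read_edge_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "gene_a"] <- "from"
  names(df)[names(df) == "gene_b"] <- "to"
  req <- c("from", "to", "combined_score")
  if (!all(req %in% names(df))) {
    stopf("'%s' lacks the edge-table columns %s", path,
          paste(req, collapse = ", "))
  }
  df[req]
}

#' @param net A `gene_network` (or bare edge data frame) to write.
#' @rdname read_edge_tsv
#' @export
write_edge_tsv <- function(net, path) {
  edges <- if (inherits(net, "gene_network")) net$edges else net
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
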