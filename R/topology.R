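#' Topological feature profile of a network
#'
#' Computes the four node-importance features used by the hub rules:
#' \describe{
#'   \item{degree}{incident edge count;}
#'   \item{betweenness}{unnormalised shortest-path betweenness on the
#'     unweighted graph, each unordered pair counted once, endpoints
#'     excluded;}
#'   \item{closeness}{by default the Wasserman-Faust component-adjusted
#'     closeness \eqn{((r-1)/\sum d) \cdot ((r-1)/(n-1))} where r is the
#'     number of reachable nodes including the node itself and \eqn{\sum d}
#'     the summed distances to them — well defined on disconnected graphs,
#'     with isolated nodes scoring 0; `closeness = "classic"` gives the
#'     within-component form \eqn{(r-1)/\sum d};}
#'   \item{kcoreness}{the largest k such that the node survives iterative
#'     removal of all nodes of degree < k.}
#' }
#' Edge scores play no role here; topology is computed on the unweighted
#' graph.
#'
#' @param net A `gene_network`.
#' @param closeness `"wasserman-faust"` (default) or `"classic"`.
#' @return A `topology_profile` data frame: `gene_id`, `degree`,
#'   `betweenness`, `closeness`, `kcoreness`.
#' @export
#' @examples
#' net <- gene_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                combined_score = c(500, 500)))
#' compute_topology(net)  # betweenness 1 for the middle node
compute_topology <- function(net, closeness = c("wasserman-faust", "classic")) {
  closeness <- match.arg(closeness)
  if (!inherits(net, "gene_network")) stopf("'net' must be a gene_network")
  n <- n_nodes(net)
  if (n == 0L) {
    res <- data.frame(gene_id = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      kcoreness = integer(), stringsAsFactors = FALSE)
    class(res) <- c("topology_profile", "data.frame")
    return(res)
  }
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  kc <- igraph::coreness(g)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    finite <- is.finite(d[i, ])
    r <- sum(finite)
    if (r <= 1L) return(0)
    sumd <- sum(d[i, finite])
    frac <- (r - 1) / sumd
    if (closeness == "wasserman-faust" && n > 1L) {
      frac * (r - 1) / (n - 1)
    } else {
      frac
    }
  }, numeric(1))
  res <- data.frame(
    gene_id = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = clo,
    kcoreness = as.integer(kc),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$gene_id), ]
  rownames(res) <- NULL
  class(res) <- c("topology_profile", "data.frame")
  res
}

#' Degree-based hub selection
#'
#' The first-stage hub rule: a node is a hub when its degree strictly
#' exceeds `multiplier` times the median degree over all profiled nodes
#' (median of an even count is the mean of the two central values).
#'
#' @param profile A `topology_profile`.
#' @param multiplier Degree multiplier (default 2: "more than two-fold of
#'   the median degree").
#' @return A `hub_selection`: list with `hub_ids` and a `criterion` record
#'   (metric medians and multiplier used).
#' @export
#' @examples
#' # star K1,5: degrees 5,1,1,1,1,1; median 1; only the center exceeds 2
#' edges <- data.frame(from = "c", to = paste0("l", 1:5), combined_score = 500)
#' select_hubs(compute_topology(gene_network(edges)))
select_hubs <- function(profile, multiplier = 2.0) {
  if (nrow(profile) == 0L) stopf("empty topology profile")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    stopf("'multiplier' must be a single positive number")
  }
  med <- hn_median(profile$degree)
  hubs <- profile$gene_id[profile$degree > multiplier * med]
  structure(
    list(hub_ids = sort(hubs),
         criterion = list(rule = "degree > multiplier * median(degree)",
                          median_degree = med, multiplier = multiplier)),
    class = "hub_selection"
  )
}

#' Major-hub selection on all four topological features
#'
#' The second-stage rule: a node is a major hub (candidate target) when its
#' degree, betweenness, closeness and k-coreness are all strictly above the
#' corresponding medians over the profiled nodes. On a vertex-transitive
#' graph every node sits at the median of every feature, so the selection is
#' empty.
#'
#' @param profile A `topology_profile`.
#' @return A `hub_selection` with the four medians recorded in `criterion`.
#' @export
select_major_hubs <- function(profile) {
  if (nrow(profile) == 0L) stopf("empty topology profile")
  meds <- c(degree = hn_median(profile$degree),
            betweenness = hn_median(profile$betweenness),
            closeness = hn_median(profile$closeness),
            kcoreness = hn_median(profile$kcoreness))
  keep <- profile$degree > meds[["degree"]] &
    profile$betweenness > meds[["betweenness"]] &
    profile$closeness > meds[["closeness"]] &
    profile$kcoreness > meds[["kcoreness"]]
  structure(
    list(hub_ids = sort(profile$gene_id[keep]),
         criterion = list(rule = "all four features > median", medians = meds)),
    class = "hub_selection"
  )
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("hub_selection: %d hubs\n", length(x$hub_ids)))
  cat("  rule:", x$criterion$rule, "\n")
  invisible(x)
}

#' Write a node-attribute table (provenance tags and metrics) as TSV
#'
#' @param profile A `topology_profile`.
#' @param path File path.
#' @param provenance Optional provenance data frame (from
#'   [assemble_candidate_network()]) merged in by `gene_id`.
#' @export
write_topology_tsv <- function(profile, path, provenance = NULL) {
  out <- as.data.frame(profile)
  if (!is.null(provenance)) {
    out <- merge(out, provenance, by = "gene_id", all.x = TRUE, sort = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
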