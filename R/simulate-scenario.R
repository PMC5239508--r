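#' Generate a complete synthetic scenario
#'
#' Runs all four generators off one master seed (each on its own derived RNG
#' stream, so artifacts never perturb each other) and completes the ground
#' truth with the planted pathway id and the planted compound targets.
#'
#' @param config A [scenario_config()].
#' @return A `scenario` list: `config`, `expression`, `network`, `pathways`,
#'   `fingerprints`, `reference_drugs`, and the completed `truth`.
#' @export
#' @examples
#' sc <- simulate_scenario(scenario_config(n_genes = 300, n_disease_genes = 40,
#'   n_network_nodes = 150, n_hub_genes = 8, disease_interactome_edges = 150,
#'   n_pathways = 10, pathway_size_range = c(5, 15), n_compounds = 6,
#'   seed = 1))
#' sc$truth
simulate_scenario <- function(config) {
  sim <- simulate_expression(config)
  truth <- sim$truth
  network <- simulate_network(config, truth)
  pathways <- simulate_pathways(config, truth)
  library <- simulate_compound_library(config, truth)
  truth$enriched_pathway_id <- attr(pathways, "planted_pathway_id")
  truth$compound_true_targets <- library$compound_targets
  validate_ground_truth(truth)
  structure(
    list(config = config,
         expression = sim$expression,
         network = network,
         pathways = pathways,
         fingerprints = library$fingerprints,
         reference_drugs = library$reference_drugs,
         truth = truth),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic scenario\n")
  print(x$expression)
  print(x$network)
  print(x$pathways)
  cat(sprintf("  %d compounds, %d reference drugs\n",
              nrow(x$fingerprints), nrow(x$reference_drugs)))
  invisible(x)
}

#' Write all scenario artifacts to a directory
#'
#' Produces the pipeline's file-based inputs: `expression.tsv` +
#' `arm_map.tsv`, `edges.tsv` (gene_a, gene_b, combined_score),
#' `pathways.gmt`, `fingerprints.tsv`, `reference_drugs.tsv`, and
#' `ground_truth.json`.
#'
#' @param scenario From [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    arm_map = file.path(dir, "arm_map.tsv"),
    edges = file.path(dir, "edges.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    fingerprints = file.path(dir, "fingerprints.tsv"),
    reference_drugs = file.path(dir, "reference_drugs.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_expression_tsv(scenario$expression, paths["expression"],
                       paths["arm_map"])
  edges_out <- scenario$network$edges
  names(edges_out) <- c("gene_a", "gene_b", "combined_score")
  write.table(edges_out, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(scenario$pathways, paths["pathways"])
  write.table(scenario$fingerprints, paths["fingerprints"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(scenario$reference_drugs, paths["reference_drugs"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(scenario$truth), paths["ground_truth"],
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a ground-truth JSON written by [write_scenario()]
#'
#' @param path File path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ground_truth(
    disease_genes = gt$disease_genes,
    reversed_by_full = gt$reversed_by_full,
    reversed_by_minus_herb = gt$reversed_by_minus_herb,
    planted_hub_genes = gt$planted_hub_genes,
    enriched_pathway_id = gt$enriched_pathway_id %||% NA_character_,
    compound_true_targets = as.list(gt$compound_true_targets)
  )
}
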