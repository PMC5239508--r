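#' Configuration for a synthetic five-arm study scenario
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the reference study conditions: five arms (control, disease model, full
#' formula, and two single-herb-deletion arms) of three replicates each, 200
#' planted disease genes shifted by 2 log2 units (half up, half down) over
#' Gaussian noise of SD 0.4, a 600-node scale-free interaction network whose
#' disease interactome carries a 20-gene planted hub module at the top of a
#' fitness hierarchy, one planted enriched pathway among 50, and a
#' 30-compound library in which half the compounds have a structurally
#' near-identical, target-annotated reference drug.
#'
#' @param n_genes Number of genes in the expression universe.
#' @param n_per_arm Replicates per arm.
#' @param n_disease_genes Number of planted disease genes (half shifted up,
#'   half down in the model arm).
#' @param effect_size Planted shift, in log2 units.
#' @param noise_sd Residual SD of log2 intensities, within arm.
#' @param reversal_fraction_full Fraction of disease genes returned to
#'   baseline by the full formula.
#' @param reversal_fraction_minus_herb Fraction returned to baseline by each
#'   herb-deletion arm (a subset of the full-formula reversals, so the
#'   difference set is attributable to the deleted herb pair).
#' @param n_network_nodes Genes carried by the interaction network (the
#'   disease genes plus a random draw of others).
#' @param attachment_parameter Edges added per node by the
#'   preferential-attachment backbone.
#' @param attachment_power Preferential-attachment exponent of the backbone;
#'   the sublinear default keeps the backbone's degree tail thinner than the
#'   planted disease hierarchy, as housekeeping interactions are less
#'   concentrated than disease-module ones.
#' @param planted_edge_score_boost Score units added to module-internal
#'   edges (combined scores are capped at 999), marking the planted module
#'   as a high-confidence complex that survives median-score filtering.
#' @param n_hub_genes Size of the planted hub module: the disease genes
#'   occupying the fitness plateau of the disease interactome.
#' @param disease_interactome_edges Edges drawn among disease genes from the
#'   hidden-fitness model.
#' @param fitness_decay Rank scale (in genes) of the exponential fitness
#'   decay below the module plateau; smaller values separate the module more
#'   sharply from the mid-tier.
#' @param module_fitness_gap Fitness ratio between the first below-module
#'   gene and the plateau, in (0, 1); the gap makes module membership
#'   unambiguous at the top of the hierarchy.
#' @param cross_edge_rate Probability that a non-disease network gene touches
#'   one random disease gene, connecting expression-selected gene sets to
#'   the disease interactome.
#' @param n_pathways Number of gene sets, the first of which is planted.
#' @param pathway_size_range Length-2 integer vector, min and max set size.
#' @param planted_pathway_overlap Fraction of the planted pathway drawn from
#'   disease genes.
#' @param n_compounds Compounds in the formula library.
#' @param n_herbs Herbs the compounds are assigned to (round robin).
#' @param fingerprint_length Fingerprint length in bits.
#' @param fingerprint_density Expected fraction of set bits in a random
#'   fingerprint.
#' @param similarity_planted Fraction of a planted compound's set bits shared
#'   by its matched reference drug. With the disjoint-remainder construction
#'   the resulting Tanimoto coefficient is `s / (2 - s)`.
#' @param seed Master seed; each artifact draws from its own stream derived
#'   from it by a fixed offset.
#'
#' @return A validated `scenario_config` object (a named list).
#' @export
#' @examples
#' cfg <- scenario_config(n_genes = 200, n_disease_genes = 20,
#'                        n_network_nodes = 100, seed = 1)
#' cfg$effect_size
scenario_config <- function(n_genes = 2000,
                            n_per_arm = 3,
                            n_disease_genes = 200,
                            effect_size = 2.0,
                            noise_sd = 0.4,
                            reversal_fraction_full = 0.9,
                            reversal_fraction_minus_herb = 0.3,
                            n_network_nodes = 600,
                            attachment_parameter = 3,
                            attachment_power = 0.5,
                            planted_edge_score_boost = 500,
                            n_hub_genes = 20,
                            disease_interactome_edges = 845,
                            fitness_decay = 25,
                            module_fitness_gap = 0.55,
                            cross_edge_rate = 0.3,
                            n_pathways = 50,
                            pathway_size_range = c(15, 60),
                            planted_pathway_overlap = 0.6,
                            n_compounds = 30,
                            n_herbs = 11,
                            fingerprint_length = 1024,
                            fingerprint_density = 0.1,
                            similarity_planted = 0.95,
                            seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_per_arm = n_per_arm,
    n_disease_genes = n_disease_genes, effect_size = effect_size,
    noise_sd = noise_sd,
    reversal_fraction_full = reversal_fraction_full,
    reversal_fraction_minus_herb = reversal_fraction_minus_herb,
    n_network_nodes = n_network_nodes,
    attachment_parameter = attachment_parameter,
    attachment_power = attachment_power,
    planted_edge_score_boost = planted_edge_score_boost,
    n_hub_genes = n_hub_genes,
    disease_interactome_edges = disease_interactome_edges,
    fitness_decay = fitness_decay,
    module_fitness_gap = module_fitness_gap,
    cross_edge_rate = cross_edge_rate,
    n_pathways = n_pathways, pathway_size_range = pathway_size_range,
    planted_pathway_overlap = planted_pathway_overlap,
    n_compounds = n_compounds, n_herbs = n_herbs,
    fingerprint_length = fingerprint_length,
    fingerprint_density = fingerprint_density,
    similarity_planted = similarity_planted,
    seed = seed
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  counts <- c("n_genes", "n_per_arm", "n_disease_genes", "n_network_nodes",
              "attachment_parameter", "n_pathways", "n_compounds", "n_herbs",
              "fingerprint_length")
  for (f in counts) {
    if (!is_count(cfg[[f]])) stopf("'%s' must be a positive integer", f)
  }
  fracs <- c("reversal_fraction_full", "reversal_fraction_minus_herb",
             "planted_pathway_overlap", "fingerprint_density",
             "similarity_planted")
  for (f in fracs) {
    if (!is_fraction(cfg[[f]])) stopf("'%s' must lie in [0, 1]", f)
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    stopf("'noise_sd' must be positive")
  }
  if (cfg$n_disease_genes > cfg$n_genes) {
    stopf("'n_disease_genes' (%d) exceeds 'n_genes' (%d)",
          cfg$n_disease_genes, cfg$n_genes)
  }
  if (cfg$n_network_nodes > cfg$n_genes) {
    stopf("'n_network_nodes' exceeds 'n_genes'")
  }
  if (cfg$n_disease_genes > cfg$n_network_nodes) {
    stopf("'n_disease_genes' exceeds 'n_network_nodes': disease genes must sit inside the network universe")
  }
  if (cfg$attachment_parameter >= cfg$n_network_nodes) {
    stopf("'attachment_parameter' must be smaller than 'n_network_nodes'")
  }
  if (cfg$n_hub_genes > cfg$n_disease_genes) {
    stopf("'n_hub_genes' exceeds 'n_disease_genes'")
  }
  if (!is_fraction(cfg$cross_edge_rate)) {
    stopf("'cross_edge_rate' must lie in [0, 1]")
  }
  if (!is.numeric(cfg$module_fitness_gap) || cfg$module_fitness_gap <= 0 ||
      cfg$module_fitness_gap >= 1) {
    stopf("'module_fitness_gap' must lie strictly in (0, 1)")
  }
  if (!is.numeric(cfg$fitness_decay) || cfg$fitness_decay <= 0) {
    stopf("'fitness_decay' must be positive")
  }
  if (!is.numeric(cfg$attachment_power) || cfg$attachment_power < 0) {
    stopf("'attachment_power' must be non-negative")
  }
  if (cfg$n_hub_genes > 0 && !is_count(cfg$disease_interactome_edges)) {
    stopf("'disease_interactome_edges' must be a positive integer")
  }
  if (length(cfg$pathway_size_range) != 2L ||
      any(cfg$pathway_size_range < 1) ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2]) {
    stopf("'pathway_size_range' must be an increasing pair of positive counts")
  }
  if (cfg$pathway_size_range[2] > cfg$n_genes) {
    stopf("'pathway_size_range' exceeds 'n_genes'")
  }
  if (cfg$fingerprint_length < 64) {
    stopf("'fingerprint_length' must be at least 64 bits")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stopf("'seed' must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario configuration\n")
  cat(sprintf("  genes: %d (%d disease, %d in hub module), %d replicates x 5 arms\n",
              x$n_genes, x$n_disease_genes, x$n_hub_genes, x$n_per_arm))
  cat(sprintf("  effect %.2g log2 units over noise SD %.2g; reversal %.0f%% (full) / %.0f%% (minus-herb)\n",
              x$effect_size, x$noise_sd, 100 * x$reversal_fraction_full,
              100 * x$reversal_fraction_minus_herb))
  cat(sprintf("  network: %d nodes, backbone m=%d (power %.2g), %d disease edges, module boost +%d\n",
              x$n_network_nodes, x$attachment_parameter, x$attachment_power,
              x$disease_interactome_edges, x$planted_edge_score_boost))
  cat(sprintf("  pathways: %d (sizes %d-%d); compounds: %d over %d herbs; seed %s\n",
              x$n_pathways, x$pathway_size_range[1], x$pathway_size_range[2],
              x$n_compounds, x$n_herbs, format(x$seed)))
  invisible(x)
}

# Arm labels used throughout: control, disease model, full formula, and the
# two single-herb-deletion arms.
SCENARIO_ARMS <- c("control", "model", "full", "minus_a", "minus_b")

new_ground_truth <- function(disease_genes, reversed_by_full,
                             reversed_by_minus_herb, planted_hub_genes,
                             enriched_pathway_id = NA_character_,
                             compound_true_targets = list()) {
  gt <- list(
    disease_genes = disease_genes,
    reversed_by_full = reversed_by_full,
    reversed_by_minus_herb = reversed_by_minus_herb,
    planted_hub_genes = planted_hub_genes,
    enriched_pathway_id = enriched_pathway_id,
    compound_true_targets = compound_true_targets
  )
  validate_ground_truth(gt)
  structure(gt, class = "ground_truth")
}

validate_ground_truth <- function(gt) {
  if (!all(gt$reversed_by_minus_herb %in% gt$reversed_by_full)) {
    stopf("ground truth violated: reversed_by_minus_herb must be a subset of reversed_by_full")
  }
  if (!all(gt$reversed_by_full %in% gt$disease_genes)) {
    stopf("ground truth violated: reversed_by_full must be a subset of disease_genes")
  }
  if (!all(gt$planted_hub_genes %in% gt$disease_genes)) {
    stopf("ground truth violated: planted_hub_genes must be disease genes")
  }
  invisible(gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Planted ground truth\n")
  cat(sprintf("  %d disease genes; %d reversed by full formula; %d by each minus-herb arm\n",
              length(x$disease_genes), length(x$reversed_by_full),
              length(x$reversed_by_minus_herb)))
  cat(sprintf("  %d hub-module genes; enriched pathway: %s; %d compounds with true targets\n",
              length(x$planted_hub_genes), x$enriched_pathway_id,
              length(x$compound_true_targets)))
  invisible(x)
}
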