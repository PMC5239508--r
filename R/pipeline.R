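#' Pipeline configuration
#'
#' Collects the file paths, thresholds and dialect switches of an
#' end-to-end run. Input files must exist at construction time; every
#' effective threshold is echoed in the run report, so there are no silent
#' defaults.
#'
#' @param expression,arm_map,edges,pathways,fingerprints,reference_drugs
#'   Input file paths (dialects as written by [write_scenario()]).
#' @param known_gene_files Character vector of plain-text gene-list files
#'   (one id per line, optional `# label` header) merged into the known
#'   disease-gene set.
#' @param out_dir Output directory for all intermediates and the report.
#' @param lfc_threshold,p_threshold DEG screening thresholds (strict
#'   inequalities; 0.5 is the screening dialect, 1.0 the two-fold dialect).
#' @param similarity_threshold Tanimoto threshold for target transfer.
#' @param degree_multiplier First-stage hub rule multiplier.
#' @param q_cutoff BH q-value cutoff used when reporting significant
#'   pathways.
#' @param closeness Closeness dialect, see [compute_topology()].
#' @param major_hub_scope Whether the four features feeding
#'   [select_major_hubs()] are computed on the hub-induced subnetwork
#'   (default, matching a selection that names the hub network first) or on
#'   the full candidate network.
#' @param var_equal Location-test dialect, see [compute_gene_stats()].
#' @param herb_pair Length-2 character vector naming the herbs whose pooled
#'   putative targets enter the herb-pair core network; defaults to the
#'   first two herb ids of the fingerprint table.
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(expression, arm_map, edges, pathways,
                            fingerprints, reference_drugs,
                            known_gene_files = character(),
                            out_dir = "pipeline_out",
                            lfc_threshold = 0.5, p_threshold = 0.05,
                            similarity_threshold = 0.85,
                            degree_multiplier = 2.0, q_cutoff = 0.05,
                            closeness = c("wasserman-faust", "classic"),
                            major_hub_scope = c("hub_subnetwork", "full_network"),
                            var_equal = TRUE,
                            herb_pair = NULL,
                            seed = 1) {
  closeness <- match.arg(closeness)
  major_hub_scope <- match.arg(major_hub_scope)
  paths <- c(expression = expression, arm_map = arm_map, edges = edges,
             pathways = pathways, fingerprints = fingerprints,
             reference_drugs = reference_drugs, known_gene_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stopf("input files not found: %s", paste(missing, collapse = ", "))
  }
  for (thr in list(lfc_threshold, p_threshold, similarity_threshold,
                   degree_multiplier, q_cutoff)) {
    if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr) || thr <= 0) {
      stopf("all thresholds must be single positive finite numbers")
    }
  }
  if (p_threshold > 1 || q_cutoff > 1 || similarity_threshold > 1) {
    stopf("probability-scale thresholds must not exceed 1")
  }
  structure(
    list(expression = expression, arm_map = arm_map, edges = edges,
         pathways = pathways, fingerprints = fingerprints,
         reference_drugs = reference_drugs,
         known_gene_files = known_gene_files, out_dir = out_dir,
         lfc_threshold = lfc_threshold, p_threshold = p_threshold,
         similarity_threshold = similarity_threshold,
         degree_multiplier = degree_multiplier, q_cutoff = q_cutoff,
         closeness = closeness, major_hub_scope = major_hub_scope,
         var_equal = var_equal, herb_pair = herb_pair, seed = seed),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, "FAILED")
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               marker)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full inference pipeline on files
#'
#' Executes the whole chain: disease-contrast DEG screening, the
#' median-score disease network and its degree hubs, treatment-contrast
#' screening and compound-target prediction, candidate-network assembly over
#' the four provenance sets, two-stage major-hub selection (the candidate
#' targets), pathway enrichment of the candidate targets, reversal
#' classification across arms, herb-pair core-gene intersection, and
#' enrichment of the core-gene network. All intermediates are written as TSV
#' under `config$out_dir`, and a machine-readable JSON report
#' (`report.json`) records sizes, thresholds (including every computed
#' median) and selected gene sets. The run is deterministic given the
#' config.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly, as a nested list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stopf("'config' must be a pipeline_config")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out, "FAILED"))
  report <- list(
    software = list(package = "herbnet",
                    version = as.character(utils::packageVersion("herbnet"))),
    config = unclass(config),
    stages = list()
  )

  expr <- pipeline_stage("read_inputs",
    read_expression_tsv(config$expression, config$arm_map), out)
  edges <- pipeline_stage("read_inputs", read_edge_tsv(config$edges), out)
  coll <- pipeline_stage("read_inputs", read_gmt(config$pathways), out)
  fps <- pipeline_stage("read_inputs",
    read_fingerprint_tsv(config$fingerprints), out)
  ref <- pipeline_stage("read_inputs",
    read_reference_drug_tsv(config$reference_drugs), out)

  # 1. disease contrast -----------------------------------------------------
  deg_model <- pipeline_stage("deg_model", {
    s <- compute_gene_stats(expr, "model", "control",
                            var_equal = config$var_equal)
    screen_degs(s, config$lfc_threshold, config$p_threshold)
  }, out)
  write_deg_tsv(deg_model, file.path(out, "deg_model_vs_control.tsv"))
  disease_degs <- deg_genes(deg_model)
  report$stages$deg_model <- list(
    contrast = "model vs control", n_genes = nrow(deg_model),
    n_up = attr(deg_model, "n_up"), n_down = attr(deg_model, "n_down"),
    thresholds = as.list(attr(deg_model, "thresholds")))

  # 2. disease network and degree hubs --------------------------------------
  disease_net <- pipeline_stage("disease_network",
    build_network(disease_degs, edges), out)
  write_edge_tsv(disease_net, file.path(out, "disease_network.tsv"))
  disease_topo <- pipeline_stage("disease_network",
    compute_topology(disease_net, closeness = config$closeness), out)
  hubs <- pipeline_stage("disease_network", {
    if (nrow(disease_topo) == 0L) stop("disease network is empty")
    select_hubs(disease_topo, config$degree_multiplier)
  }, out)
  write_topology_tsv(disease_topo, file.path(out, "disease_topology.tsv"))
  report$stages$disease_network <- list(
    n_nodes = n_nodes(disease_net), n_edges = n_edges(disease_net),
    score_threshold = attr(disease_net, "score_threshold"),
    median_degree = hubs$criterion$median_degree,
    degree_multiplier = hubs$criterion$multiplier,
    n_hubs = length(hubs$hub_ids), hub_genes = hubs$hub_ids)

  # 3. treatment contrast + target prediction -------------------------------
  deg_treat <- pipeline_stage("deg_treatment", {
    s <- compute_gene_stats(expr, "full", "model",
                            var_equal = config$var_equal)
    screen_degs(s, config$lfc_threshold, config$p_threshold)
  }, out)
  write_deg_tsv(deg_treat, file.path(out, "deg_full_vs_model.tsv"))
  treat_genes <- deg_genes(deg_treat)
  report$stages$deg_treatment <- list(
    contrast = "full vs model", n_up = attr(deg_treat, "n_up"),
    n_down = attr(deg_treat, "n_down"),
    n_regulating = length(treat_genes))

  preds <- pipeline_stage("target_prediction",
    predict_compound_targets(fps, ref, config$similarity_threshold), out)
  write.table(preds, file.path(out, "target_predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  herb_map <- setNames(fps$herb_id, fps$compound_id)
  profile <- pipeline_stage("target_prediction",
    herb_target_profile(preds, herb_map), out)
  write.table(profile$counts, file.path(out, "herb_target_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  putative <- profile$formula_targets
  report$stages$target_prediction <- list(
    similarity_threshold = config$similarity_threshold,
    n_predictions = nrow(preds), n_putative_targets = length(putative),
    herb_counts = setNames(as.list(profile$counts$n_targets),
                           profile$counts$herb_id))

  # 4. known genes -----------------------------------------------------------
  known <- pipeline_stage("known_genes", {
    if (length(config$known_gene_files)) {
      lists <- lapply(config$known_gene_files, read_gene_list)
      names(lists) <- vapply(lists, attr, character(1), "label")
      merge_known_genes(lists)$gene_ids
    } else character()
  }, out)
  report$stages$known_genes <- list(n_known = length(known),
                                    known_genes = known)

  # 5. candidate network and two-stage hub selection -------------------------
  cand_net <- pipeline_stage("candidate_network",
    assemble_candidate_network(hubs$hub_ids, known, treat_genes, putative,
                               edges), out)
  write_edge_tsv(cand_net, file.path(out, "candidate_network.tsv"))
  cand_topo <- pipeline_stage("candidate_network",
    compute_topology(cand_net, closeness = config$closeness), out)
  cand_hubs <- pipeline_stage("candidate_network", {
    if (nrow(cand_topo) == 0L) stop("candidate network is empty")
    select_hubs(cand_topo, config$degree_multiplier)
  }, out)
  hub_net <- pipeline_stage("candidate_network",
    induce_subnetwork(cand_net, cand_hubs$hub_ids), out)
  write_edge_tsv(hub_net, file.path(out, "candidate_hub_network.tsv"))
  major_profile <- if (config$major_hub_scope == "hub_subnetwork") {
    topo <- compute_topology(hub_net, closeness = config$closeness)
    write_topology_tsv(topo, file.path(out, "candidate_hub_topology.tsv"),
                       provenance = cand_net$provenance)
    topo
  } else {
    cand_topo[cand_topo$gene_id %in% cand_hubs$hub_ids, , drop = FALSE]
  }
  major <- pipeline_stage("candidate_network", {
    if (nrow(major_profile) == 0L) stop("candidate hub network is empty")
    select_major_hubs(major_profile)
  }, out)
  candidate_targets <- major$hub_ids
  writeLines(candidate_targets, file.path(out, "candidate_targets.txt"))
  report$stages$candidate_network <- list(
    n_nodes = n_nodes(cand_net), n_edges = n_edges(cand_net),
    score_threshold = attr(cand_net, "score_threshold"),
    median_degree = cand_hubs$criterion$median_degree,
    n_hub_nodes = length(cand_hubs$hub_ids),
    hub_network = list(n_nodes = n_nodes(hub_net),
                       n_edges = n_edges(hub_net)),
    major_hub_scope = config$major_hub_scope,
    feature_medians = as.list(major$criterion$medians),
    n_candidate_targets = length(candidate_targets),
    candidate_targets = candidate_targets)

  # 6. enrichment of candidate targets ---------------------------------------
  enr <- pipeline_stage("enrichment", {
    if (length(intersect(candidate_targets, coll$universe)) == 0L) {
      warnf("no candidate targets in the pathway universe; skipping enrichment")
      NULL
    } else {
      enrich_pathways(candidate_targets, coll)
    }
  }, out)
  if (is.null(enr)) {
    enr <- data.frame(pathway_id = character(), qvalue = numeric())
  }
  write_enrichment_tsv(enr, file.path(out, "candidate_target_enrichment.tsv"))
  report$stages$enrichment <- list(
    q_cutoff = config$q_cutoff,
    n_significant = sum(enr$qvalue < config$q_cutoff),
    top_pathway = if (nrow(enr)) enr$pathway_id[1] else NA_character_,
    top_qvalue = if (nrow(enr)) enr$qvalue[1] else NA_real_)

  # 7. reversal classification ----------------------------------------------
  reversal <- pipeline_stage("reversal", {
    tab <- classify_reversal(deg_model, deg_treat)
    minus_a <- screen_degs(
      compute_gene_stats(expr, "minus_a", "full", var_equal = config$var_equal),
      config$lfc_threshold, config$p_threshold)
    minus_b <- screen_degs(
      compute_gene_stats(expr, "minus_b", "full", var_equal = config$var_equal),
      config$lfc_threshold, config$p_threshold)
    tab$minus_a_direction <- minus_a$direction[match(tab$gene_id,
                                                     minus_a$gene_id)]
    tab$minus_b_direction <- minus_b$direction[match(tab$gene_id,
                                                     minus_b$gene_id)]
    list(table = tab, minus_a = minus_a, minus_b = minus_b)
  }, out)
  write_reversal_tsv(reversal$table, file.path(out, "reversal.tsv"))
  write_deg_tsv(reversal$minus_a, file.path(out, "deg_minus_a_vs_full.tsv"))
  write_deg_tsv(reversal$minus_b, file.path(out, "deg_minus_b_vs_full.tsv"))
  report$stages$reversal <- list(
    n_reversed = sum(reversal$table$category == "reversed"),
    n_not_reversed = sum(reversal$table$category == "not_reversed"),
    n_unaffected = sum(reversal$table$category == "unaffected"))

  # 8. herb-pair core genes and core network ---------------------------------
  core <- pipeline_stage("herb_pair",
    herb_pair_core_genes(reversal$minus_a, reversal$minus_b), out)
  writeLines(core, file.path(out, "herb_pair_core_genes.txt"))
  pair <- config$herb_pair %||% head(sort(unique(fps$herb_id)), 2)
  pair_targets <- sort(unique(unlist(profile$herb_targets[pair])))
  core_net <- pipeline_stage("herb_pair", {
    if (length(c(hubs$hub_ids, known, core, pair_targets)) == 0L) {
      stop("no genes available for the core network")
    }
    assemble_candidate_network(hubs$hub_ids, known, core, pair_targets, edges)
  }, out)
  write_edge_tsv(core_net, file.path(out, "herb_pair_core_network.tsv"))
  core_enr <- pipeline_stage("herb_pair", {
    if (length(intersect(core_net$nodes, coll$universe)) == 0L) NULL
    else enrich_pathways(core_net$nodes, coll)
  }, out)
  if (!is.null(core_enr)) {
    write_enrichment_tsv(core_enr, file.path(out, "herb_pair_enrichment.tsv"))
  }
  report$stages$herb_pair <- list(
    herb_pair = pair, n_core_genes = length(core), core_genes = core,
    n_pair_putative_targets = length(pair_targets),
    core_network = list(n_nodes = n_nodes(core_net),
                        n_edges = n_edges(core_net)),
    top_pathway = if (is.null(core_enr)) NA_character_ else core_enr$pathway_id[1],
    top_qvalue = if (is.null(core_enr)) NA_real_ else core_enr$qvalue[1])

  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
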