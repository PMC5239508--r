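#' Simulate gene-set collections with one planted enriched pathway
#'
#' Draws `n_pathways` gene sets over the expression universe with sizes
#' uniform in `pathway_size_range`. The first pathway is planted: a fraction
#' `planted_pathway_overlap` of its members are disease genes — the hub
#' module first, then other disease genes — far above the chance rate, so it
#' surfaces both in an over-representation test of a disease-gene-rich query
#' and in the enrichment of the topologically selected candidate targets.
#' All remaining pathways are uniform draws from the universe.
#'
#' @param config A [scenario_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return A [pathway_collection()]; the planted pathway id is recorded in
#'   the `planted_pathway_id` attribute.
#' @export
simulate_pathways <- function(config, truth) {
  validate_scenario_config(config)
  set_stream(config$seed, "pathways")

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  sizes <- sample(seq(config$pathway_size_range[1],
                      config$pathway_size_range[2]),
                  config$n_pathways, replace = TRUE)
  ids <- sprintf("PW%03d", seq_len(config$n_pathways))

  sets <- vector("list", config$n_pathways)
  names(sets) <- ids

  n_dis <- min(round(config$planted_pathway_overlap * sizes[1]),
               length(truth$disease_genes))
  dis_part <- c(truth$planted_hub_genes,
                sample(setdiff(truth$disease_genes, truth$planted_hub_genes)))
  dis_part <- dis_part[seq_len(n_dis)]
  planted <- c(dis_part,
               sample(setdiff(genes, truth$disease_genes), sizes[1] - n_dis))
  sets[[1]] <- sort(planted)
  for (i in seq_len(config$n_pathways)[-1]) {
    sets[[i]] <- sort(sample(genes, sizes[i]))
  }

  coll <- pathway_collection(
    sets, universe = genes,
    names = setNames(sprintf("synthetic pathway %03d", seq_along(ids)), ids)
  )
  attr(coll, "planted_pathway_id") <- ids[1]
  coll
}
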