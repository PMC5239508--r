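# Shared fixture builders. Everything is generated in code at test time.

small_config <- function(seed = 1, ...) {
  args <- modifyList(
    list(n_genes = 300, n_disease_genes = 40, n_network_nodes = 150,
         n_hub_genes = 8, disease_interactome_edges = 170,
         n_pathways = 10, pathway_size_range = c(5, 15),
         n_compounds = 8, fingerprint_length = 256, seed = seed),
    list(...))
  do.call(scenario_config, args)
}

tiny_expression <- function(values, arms) {
  expression_matrix(values, arms)
}

# 2-arm matrix with given per-gene group values (lists of length-n vectors)
two_arm_matrix <- function(case, control, genes = NULL) {
  stopifnot(nrow(case) == nrow(control))
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(case)))
  colnames(case) <- paste0("case_", seq_len(ncol(case)))
  colnames(control) <- paste0("ctl_", seq_len(ncol(control)))
  values <- cbind(case, control)
  rownames(values) <- genes
  arms <- setNames(rep(c("case", "ctl"), c(ncol(case), ncol(control))),
                   colnames(values))
  expression_matrix(values, arms)
}

# Render an expression matrix in GEO series-matrix dialect (synthetic stand-in
# for a downloaded series matrix; text only, built in memory).
write_synthetic_series_matrix <- function(expr, path) {
  samples <- colnames(expr$values)
  gsm <- sprintf("GSM%06d", seq_along(samples))
  lines <- c(
    "!Series_title\t\"synthetic five-arm goiter study export\"",
    "!Series_platform_id\t\"GPL0000\"",
    paste0("!Sample_title\t", paste(sprintf('"%s"', samples), collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf('"%s"', gsm)), collapse = "\t")
  )
  body <- apply(cbind(sprintf('"%s"', rownames(expr$values)),
                      format(expr$values, trim = TRUE, digits = 8)),
                1, paste, collapse = "\t")
  writeLines(c(lines, body, "!series_matrix_table_end"), path)
  setNames(unname(expr$arms), gsm)  # arm map keyed by GSM accession
}

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
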