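#' Construct an expression matrix with arm labels
#'
#' Container for log2-scale intensities: a numeric matrix with genes in rows,
#' samples in columns, and a sample-to-arm map. Values are assumed already
#' normalised; no probe collapsing or background correction happens here.
#'
#' @param values Numeric matrix, genes x samples, with row and column names.
#' @param arms Named character vector mapping every sample id to one arm
#'   label.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, arms) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  if (!all(is.finite(values))) stopf("all expression values must be finite")
  arms <- unlist(arms)
  missing <- setdiff(colnames(values), names(arms))
  if (length(missing)) {
    stopf("samples without an arm label: %s", paste(missing, collapse = ", "))
  }
  arms <- arms[colnames(values)]
  structure(
    list(values = values, arms = arms),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$arms)
  cat("  arms:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)

sample_ids <- function(expr) colnames(expr$values)

arm_samples <- function(expr, arm) {
  ids <- names(expr$arms)[expr$arms == arm]
  if (!length(ids)) stopf("unknown or empty arm label '%s'", arm)
  ids
}

#' Simulate five-arm expression data with planted disease genes
#'
#' Draws log2 intensities for the five study arms. Control samples sit at a
#' gene-specific baseline; the model arm shifts the planted disease genes by
#' `effect_size` (half up, half down); the full-formula arm returns
#' `reversal_fraction_full` of the disease genes to baseline; each
#' herb-deletion arm returns only the `reversal_fraction_minus_herb` subset,
#' drawn from within the full-formula reversals so that the containment chain
#' `reversed_by_minus_herb` within `reversed_by_full` within `disease_genes`
#' holds by construction. Non-disease genes are identically distributed in
#' every arm.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (a `ground_truth` whose pathway and compound fields are filled
#'   by the corresponding generators, or by [simulate_scenario()]).
#' @export
#' @examples
#' sim <- simulate_expression(scenario_config(n_genes = 100,
#'   n_disease_genes = 10, n_network_nodes = 50, n_hub_genes = 4, seed = 1))
#' dim(sim$expression)
simulate_expression <- function(config) {
  validate_scenario_config(config)
  set_stream(config$seed, "expression")

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  disease <- sort(sample(genes, config$n_disease_genes))
  n_up <- ceiling(config$n_disease_genes / 2)
  up_genes <- disease[seq_len(n_up)]
  sign_of <- setNames(rep(-1, config$n_disease_genes), disease)
  sign_of[up_genes] <- 1

  hub_genes <- disease[seq_len(config$n_hub_genes)]
  n_full <- round(config$reversal_fraction_full * config$n_disease_genes)
  reversed_full <- sort(sample(disease, n_full))
  n_minus <- round(config$reversal_fraction_minus_herb * config$n_disease_genes)
  n_minus <- min(n_minus, n_full)
  reversed_minus <- sort(sample(reversed_full, n_minus))

  baseline <- rnorm(config$n_genes, mean = 8, sd = 1.5)
  names(baseline) <- genes

  shift <- setNames(numeric(config$n_genes), genes)
  shift[disease] <- sign_of[disease] * config$effect_size

  # Per-arm mean profiles: reversal means the arm's mean returns to baseline.
  arm_mean <- cbind(
    control = baseline,
    model   = baseline + shift,
    full    = baseline + shift * !(genes %in% reversed_full),
    minus_a = baseline + shift * !(genes %in% reversed_minus),
    minus_b = baseline + shift * !(genes %in% reversed_minus)
  )

  n <- config$n_per_arm
  samples <- as.vector(vapply(SCENARIO_ARMS, function(a) {
    paste0(a, "_", seq_len(n))
  }, character(n)))
  arms <- setNames(rep(SCENARIO_ARMS, each = n), samples)

  mu <- arm_mean[, arms[samples], drop = FALSE]
  values <- mu + matrix(rnorm(length(mu), sd = config$noise_sd),
                        nrow = nrow(mu))
  dimnames(values) <- list(genes, samples)

  truth <- new_ground_truth(
    disease_genes = disease,
    reversed_by_full = reversed_full,
    reversed_by_minus_herb = reversed_minus,
    planted_hub_genes = hub_genes
  )
  list(expression = expression_matrix(values, arms), truth = truth)
}
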