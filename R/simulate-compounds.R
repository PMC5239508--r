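#' Simulate a formula compound library with planted reference-drug analogues
#'
#' Assigns `n_compounds` compounds round-robin to `n_herbs` herbs and gives
#' each a random binary fingerprint with expected bit density
#' `fingerprint_density`. For the first half of the compounds a matched
#' reference drug is planted: it shares `similarity_planted` of the
#' compound's set bits and replaces the rest with bits disjoint from the
#' compound, keeping the set-bit count, so the pair's Tanimoto coefficient is
#' `s / (2 - s)` up to rounding. The matched drug is annotated with 3-6 true
#' target genes drawn from the disease genes. An equal number of decoy
#' reference drugs carry independent random fingerprints and random target
#' annotations.
#'
#' @param config A [scenario_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return List with `fingerprints` (compound table), `reference_drugs`
#'   (drug table), and `compound_targets` (named list: compound id to its
#'   planted true target genes) for merging into the ground truth.
#' @export
simulate_compound_library <- function(config, truth) {
  validate_scenario_config(config)
  set_stream(config$seed, "compounds")

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  L <- config$fingerprint_length
  cpds <- sprintf("cpd%03d", seq_len(config$n_compounds))
  herbs <- sprintf("herb%02d", rep_len(seq_len(config$n_herbs),
                                       config$n_compounds))

  rand_fp <- function() runif(L) < config$fingerprint_density
  cpd_fps <- lapply(cpds, function(i) {
    fp <- rand_fp()
    if (!any(fp)) fp[sample(L, 1L)] <- TRUE  # similarity needs >= 1 set bit
    fp
  })
  names(cpd_fps) <- cpds

  n_planted <- ceiling(config$n_compounds / 2)
  planted_cpds <- cpds[seq_len(n_planted)]
  compound_targets <- list()
  ref_rows <- list()
  for (i in seq_along(planted_cpds)) {
    cid <- planted_cpds[i]
    fp <- cpd_fps[[cid]]
    set_idx <- which(fp)
    b <- length(set_idx)
    shared <- round(config$similarity_planted * b)
    ref_fp <- logical(L)
    if (shared > 0) ref_fp[sample(set_idx, shared)] <- TRUE
    off <- which(!fp)
    extra <- min(b - shared, length(off))
    if (extra > 0) ref_fp[sample(off, extra)] <- TRUE
    tg <- sort(sample(truth$disease_genes, sample(3:6, 1L)))
    compound_targets[[cid]] <- tg
    ref_rows[[i]] <- data.frame(
      drug_id = sprintf("ref%03d", i),
      fingerprint = fp_to_hex(ref_fp),
      targets = paste(tg, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  n_decoy <- n_planted
  for (j in seq_len(n_decoy)) {
    fp <- rand_fp()
    if (!any(fp)) fp[sample(L, 1L)] <- TRUE
    ref_rows[[n_planted + j]] <- data.frame(
      drug_id = sprintf("decoy%03d", j),
      fingerprint = fp_to_hex(fp),
      targets = paste(sort(sample(genes, sample(3:6, 1L))), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }

  fingerprints <- data.frame(
    compound_id = cpds,
    herb_id = herbs,
    fingerprint = vapply(cpd_fps, fp_to_hex, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(fingerprints) <- NULL
  list(fingerprints = fingerprints,
       reference_drugs = do.call(rbind, ref_rows),
       compound_targets = compound_targets)
}
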