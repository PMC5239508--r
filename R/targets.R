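#' Tanimoto similarity of two binary fingerprints
#'
#' The Jaccard coefficient over set bits: size of the intersection over size
#' of the union. Undefined when both fingerprints are all-zero.
#'
#' @param a,b Logical vectors of equal length (or objects coercible to
#'   logical), bit i set meaning feature i present.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' a <- c(TRUE, TRUE, TRUE, FALSE)
#' b <- c(FALSE, TRUE, TRUE, TRUE)
#' tanimoto(a, b)  # 2/4
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stopf("fingerprint lengths differ (%d vs %d)", length(a), length(b))
  }
  uni <- sum(a | b)
  if (uni == 0L) stopf("both fingerprints are all-zero; Tanimoto undefined")
  sum(a & b) / uni
}

#' Encode / decode fingerprints as hex strings
#'
#' Bits are packed little-endian within each byte (bit 1 of the vector is the
#' least significant bit of the first byte) and rendered as lower-case hex,
#' two characters per byte. Length must be a multiple of 8.
#'
#' @param bits Logical vector.
#' @return `fp_to_hex()` a hex string; `hex_to_fp()` the logical vector.
#' @export
fp_to_hex <- function(bits) {
  bits <- as.logical(bits)
  if (length(bits) %% 8 != 0) stopf("fingerprint length must be a multiple of 8")
  paste(sprintf("%02x", as.integer(packBits(bits, type = "raw"))),
        collapse = "")
}

#' @param hex Hex string from `fp_to_hex()`.
#' @rdname fp_to_hex
#' @export
hex_to_fp <- function(hex) {
  if (!grepl("^[0-9a-fA-F]+$", hex) || nchar(hex) %% 2 != 0) {
    stopf("not a valid hex fingerprint")
  }
  bytes <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L))
  as.logical(rawToBits(bytes))
}

decode_fp_table <- function(df, id_col, hex_col = "fingerprint") {
  fps <- lapply(df[[hex_col]], hex_to_fp)
  lens <- unique(lengths(fps))
  if (length(lens) != 1L) stopf("fingerprints have mixed bit lengths")
  m <- do.call(rbind, fps)
  rownames(m) <- df[[id_col]]
  if (any(rowSums(m) == 0L)) {
    stopf("all-zero fingerprints are not scoreable: %s",
          paste(head(df[[id_col]][rowSums(m) == 0L], 5), collapse = ", "))
  }
  m
}

#' Predict compound targets by similarity transfer from reference drugs
#'
#' Implements the structure-similarity hypothesis — compounds whose chemical
#' fingerprints closely match a target-annotated reference drug inherit that
#' drug's targets. Every (compound, reference drug) pair with Tanimoto
#' similarity at or above `threshold` contributes one prediction row per
#' annotated target gene.
#'
#' @param fps Fingerprint table: data frame with columns `compound_id`,
#'   `herb_id`, `fingerprint` (hex).
#' @param ref Reference-drug table: data frame with columns `drug_id`,
#'   `fingerprint` (hex), `targets` (semicolon-joined gene ids).
#' @param threshold Minimum Tanimoto similarity, in `(0, 1]`.
#' @return Data frame with columns `compound_id`, `herb_id`, `gene_id`,
#'   `similarity`, `source_drug_id`; zero rows (with a warning) when the
#'   reference table is empty.
#' @export
predict_compound_targets <- function(fps, ref, threshold = 0.85) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stopf("'threshold' must lie in (0, 1]")
  }
  empty <- data.frame(compound_id = character(), herb_id = character(),
                      gene_id = character(), similarity = numeric(),
                      source_drug_id = character(), stringsAsFactors = FALSE)
  if (is.null(ref) || nrow(ref) == 0L) {
    warnf("empty reference-drug table; no targets can be predicted")
    return(empty)
  }
  fmat <- decode_fp_table(fps, "compound_id")
  rmat <- decode_fp_table(ref, "drug_id")
  if (ncol(fmat) != ncol(rmat)) {
    stopf("fingerprint lengths differ between compounds (%d) and reference drugs (%d)",
          ncol(fmat), ncol(rmat))
  }
  inter <- fmat %*% t(rmat)
  union <- outer(rowSums(fmat), rowSums(rmat), `+`) - inter
  sim <- inter / union
  hits <- which(sim >= threshold, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  herb_of <- setNames(fps$herb_id, fps$compound_id)
  target_of <- strsplit(ref$targets, ";", fixed = TRUE)
  names(target_of) <- ref$drug_id
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    cid <- rownames(fmat)[hits[i, 1]]
    did <- rownames(rmat)[hits[i, 2]]
    genes <- target_of[[did]]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) return(NULL)
    data.frame(compound_id = cid, herb_id = unname(herb_of[cid]),
               gene_id = genes, similarity = sim[hits[i, 1], hits[i, 2]],
               source_drug_id = did, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$compound_id, out$gene_id, out$source_drug_id), ]
  rownames(out) <- NULL
  out
}

#' Aggregate target predictions per herb and for the whole formula
#'
#' Unions predicted genes over each herb's compounds and over the full
#' formula, reporting per-herb counts. Compounds present in the prediction
#' table but missing from the herb map are an error.
#'
#' @param preds Prediction table from [predict_compound_targets()].
#' @param herb_map Named character vector, compound id to herb id.
#' @return List with `herb_targets` (named list of gene-id vectors),
#'   `formula_targets` (union), and `counts` (data frame herb_id / n_targets).
#' @export
herb_target_profile <- function(preds, herb_map) {
  unmapped <- setdiff(unique(preds$compound_id), names(herb_map))
  if (length(unmapped)) {
    stopf("compounds without a herb assignment: %s",
          paste(unmapped, collapse = ", "))
  }
  herbs <- sort(unique(unname(herb_map)))
  herb_targets <- lapply(setNames(herbs, herbs), function(h) {
    cpds <- names(herb_map)[herb_map == h]
    sort(unique(preds$gene_id[preds$compound_id %in% cpds]))
  })
  formula_targets <- sort(unique(unlist(herb_targets)))
  counts <- data.frame(herb_id = herbs,
                       n_targets = unname(lengths(herb_targets)),
                       stringsAsFactors = FALSE)
  list(herb_targets = herb_targets, formula_targets = formula_targets,
       counts = counts)
}

#' Read / write fingerprint and reference-drug tables
#'
#' Tab-separated with headers `compound_id`, `herb_id`, `fingerprint` and
#' `drug_id`, `fingerprint`, `targets` respectively; fingerprints hex-encoded
#' ([fp_to_hex()]), targets semicolon-joined.
#'
#' @param path File path.
#' @return The data frame read.
#' @export
read_fingerprint_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  req <- c("compound_id", "herb_id", "fingerprint")
  if (!all(req %in% names(df))) {
    stopf("'%s' lacks fingerprint-table columns %s", path,
          paste(req, collapse = ", "))
  }
  df[req]
}

#' @rdname read_fingerprint_tsv
#' @export
read_reference_drug_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("drug_id", "fingerprint", "targets")
  if (!all(req %in% names(df))) {
    stopf("'%s' lacks reference-drug columns %s", path,
          paste(req, collapse = ", "))
  }
  df[req]
}
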