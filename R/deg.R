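#' Per-gene two-arm contrast statistics
#'
#' Computes, for every gene, the log2 fold change (case mean minus control
#' mean — inputs are already log2 scale) and a two-sided two-sample t-test
#' p-value. The default is the pooled-variance Student t, which is exact
#' under the homoskedastic Gaussian model and keeps its nominal size at the
#' three-replicate group sizes typical of pooled-array designs;
#' `var_equal = FALSE` switches to Welch/Satterthwaite for unequal-variance
#' robustness at larger n.
#'
#' Genes with zero variance in both arms get p = 1 when the means are equal;
#' otherwise the variance is floored at 1e-12 so a real shift is not hidden
#' by a degenerate denominator.
#'
#' @param expr An [expression_matrix()].
#' @param case_arm,control_arm Arm labels; each needs at least two samples.
#' @param var_equal Use the pooled-variance t (default) or Welch.
#' @return A `deg_table` data frame: `gene_id`, `log2fc`, `pvalue`,
#'   `direction` (all `NA` until [screen_degs()] assigns calls).
#' @export
compute_gene_stats <- function(expr, case_arm, control_arm, var_equal = TRUE) {
  if (!inherits(expr, "expression_matrix")) {
    stopf("'expr' must be an expression_matrix")
  }
  for (arm in c(case_arm, control_arm)) {
    if (!arm %in% expr$arms) stopf("unknown arm label '%s'", arm)
    if (sum(expr$arms == arm) < 2L) {
      stopf("arm '%s' has fewer than 2 samples", arm)
    }
  }
  x <- expr$values[, arm_samples(expr, case_arm), drop = FALSE]
  y <- expr$values[, arm_samples(expr, control_arm), drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  lfc <- mx - my

  both_const <- vx == 0 & vy == 0
  vx_f <- pmax(vx, 1e-12)
  vy_f <- pmax(vy, 1e-12)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx_f + (ny - 1) * vy_f) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(lfc))
  } else {
    se2 <- vx_f / nx + vy_f / ny
    se <- sqrt(se2)
    df <- se2^2 / ((vx_f / nx)^2 / (nx - 1) + (vy_f / ny)^2 / (ny - 1))
  }
  p <- 2 * pt(-abs(lfc / se), df)
  p[both_const & lfc == 0] <- 1

  res <- data.frame(
    gene_id = gene_ids(expr),
    log2fc = unname(lfc),
    pvalue = unname(p),
    direction = NA_character_,
    stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- c(case = case_arm, control = control_arm)
  class(res) <- c("deg_table", "data.frame")
  res
}

#' Screen differentially expressed genes
#'
#' Applies the joint screening rule with strict inequalities: a gene is
#' called `up` when `log2fc > lfc_threshold` and `pvalue < p_threshold`,
#' `down` when `log2fc < -lfc_threshold` and `pvalue < p_threshold`, and `ns`
#' otherwise. Values exactly at a threshold are not called. Raw p-values are
#' screened by default; `adjust = "BH"` screens Benjamini-Hochberg-adjusted
#' values instead.
#'
#' @param stats A `deg_table` from [compute_gene_stats()].
#' @param lfc_threshold Positive log2 fold-change threshold. The default 0.5
#'   is the screening dialect; 1.0 is the stricter two-fold dialect.
#' @param p_threshold Positive p-value threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The table with `direction` set; attributes `n_up` / `n_down`
#'   carry the counts.
#' @export
screen_degs <- function(stats, lfc_threshold = 0.5, p_threshold = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  for (thr in c(lfc_threshold, p_threshold)) {
    if (!is.numeric(thr) || length(thr) != 1L || !is.finite(thr) || thr <= 0) {
      stopf("screening thresholds must be single positive finite numbers")
    }
  }
  p <- if (adjust == "BH") p.adjust(stats$pvalue, method = "BH") else stats$pvalue
  sig <- p < p_threshold
  stats$direction <- ifelse(sig & stats$log2fc > lfc_threshold, "up",
                     ifelse(sig & stats$log2fc < -lfc_threshold, "down", "ns"))
  attr(stats, "thresholds") <- c(lfc = lfc_threshold, p = p_threshold)
  attr(stats, "adjust") <- adjust
  attr(stats, "n_up") <- sum(stats$direction == "up")
  attr(stats, "n_down") <- sum(stats$direction == "down")
  stats
}

#' Dysregulated genes of a screened table
#'
#' @param stats A screened `deg_table`.
#' @param direction `"both"` (up or down), `"up"`, or `"down"`.
#' @return Character vector of gene ids.
#' @export
deg_genes <- function(stats, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (all(is.na(stats$direction))) {
    stopf("directions are unset; run screen_degs() first")
  }
  keep <- switch(direction,
                 both = stats$direction %in% c("up", "down"),
                 up = stats$direction == "up",
                 down = stats$direction == "down")
  sort(stats$gene_id[keep])
}

#' @export
print.deg_table <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("deg_table: %d genes", nrow(x)))
  if (!is.null(ct)) cat(sprintf(" (%s vs %s)", ct[["case"]], ct[["control"]]))
  cat("\n")
  if (!all(is.na(x$direction))) {
    cat(sprintf("  up: %d, down: %d, ns: %d\n",
                sum(x$direction == "up"), sum(x$direction == "down"),
                sum(x$direction == "ns")))
  } else {
    cat("  directions unset (run screen_degs)\n")
  }
  invisible(x)
}

#' Read / write DEG tables as TSV
#'
#' Columns `gene_id`, `log2fc`, `pvalue`, `direction`.
#'
#' @param path File path.
#' @return `read_deg_tsv()` returns a `deg_table`.
#' @export
read_deg_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "log2fc", "pvalue", "direction")
  if (!all(req %in% names(df))) {
    stopf("'%s' lacks DEG columns %s", path, paste(req, collapse = ", "))
  }
  df <- df[req]
  class(df) <- c("deg_table", "data.frame")
  df
}

#' @param stats A `deg_table` to write.
#' @rdname read_deg_tsv
#' @export
write_deg_tsv <- function(stats, path) {
  write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
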