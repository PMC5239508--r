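`%||%` <- function(x, y) if (is.null(x)) y else x

# Median convention used by every selection rule: even counts average the two
# central order statistics (stats::median default). Centralised so hub rules
# and edge thresholds cannot drift apart.
hn_median <- function(x) stats::median(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_fraction <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# Derived RNG streams: one fixed offset per generated artifact so adding an
# artifact never perturbs the others. Master seeds are expected small; the
# offsets keep the effective seed well inside 32-bit integer range.
RNG_STREAM <- c(expression = 0L, network = 1L, pathways = 2L, compounds = 3L)

set_stream <- function(seed, stream) {
  offset <- RNG_STREAM[[stream]]
  set.seed(as.integer(seed) + offset)
}

canonical_pair <- function(a, b) {
  swap <- a > b
  list(from = ifelse(swap, b, a), to = ifelse(swap, a, b))
}
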