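# Internal helpers shared across stages.

# Stage-level logging goes through rlang::inform so tests can muffle it with
# suppressMessages() and callers can sink it via the usual condition system.
log_msg <- function(..., .verbose = getOption("clustermod.verbose", TRUE)) {
  if (isTRUE(.verbose)) inform(paste0(...))
}

# Fixed-precision float rendering used by every report writer: 6 significant
# digits, so that byte-identical reruns are achievable across platforms.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Adjusted Rand index between two label vectors (thin wrapper; mclust is the
# field-standard implementation).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
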