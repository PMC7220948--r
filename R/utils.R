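#' @keywords internal
"_PACKAGE"

# Deterministic per-repeat seed derivation. A Lehmer-style mixing step keeps
# every derived seed in [1, 2^31 - 2] so it is always a valid R RNG seed and
# distinct repeats of the same master seed get well-separated streams.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(master_seed) %% m + m) %% m
  x <- (x * 48271 + as.numeric(index) * 69621 + 1) %% m
  as.integer((x * 16807) %% m)
}

# Standardise columns of a samples x genes matrix using supplied (or its own)
# means/sds. Zero-variance columns are an error: a constant gene carries no
# information and makes downstream weights undefined.
standardise_cols <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) scale <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(scale) | scale <= 0)
  if (length(bad) > 0) {
    stop("zero-variance gene(s): ", paste(colnames(x)[bad], collapse = ", "))
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
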