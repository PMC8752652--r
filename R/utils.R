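#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG seed, restoring the caller's RNG state.
# All randomized operations in the package go through this so that no
# function mutates the global random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-sample seed derived from a master seed and an index.
# Mixed multiplicative hash, kept inside the 32-bit signed integer range.
derive_seed <- function(master_seed, index) {
  h <- (as.numeric(master_seed) %% 2147483647) * 48271 +
    (as.numeric(index) + 1) * 69621
  as.integer(h %% 2147483647)
}

# Shannon entropy of a probability vector, 0 log 0 := 0, natural log.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log(p))
}

# Requantize a gray-level image to G levels in 0..G-1.
# Integer images whose range already fits within G levels are only shifted
# to start at 0; wider or non-integer ranges are binned linearly.
quantize_gray <- function(img, G = 32L) {
  stopifnot(G >= 2L)
  v <- img - min(img)
  mx <- max(v)
  if (mx == 0) return(array(0L, dim = dim(img)))
  if (mx <= G - 1 && all(v == round(v))) {
    q <- v
  } else {
    q <- floor(v * G / (mx * (1 + 1e-12)))
  }
  q <- pmin(pmax(q, 0), G - 1)
  array(as.integer(q), dim = dim(img))
}

# z-score columns; zero-variance columns map to 0 (not NaN).
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
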