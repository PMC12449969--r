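# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator calls do not perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Standardize columns to zero mean / unit variance
#'
#' Returns the standardized matrix with the centering and scaling vectors as
#' attributes; constant columns are scaled by 1 to avoid division by zero.
#' @noRd
standardize_columns <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  Xs
}

# Moving-average smoother with edge-truncated windows (no phase shift).
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- width %/% 2
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Adjusted Rand index between two label vectors (Hubert & Arabie).
# mclust provides the same statistic; kept thin here so tree internals do
# not need a hard dependency at every call site.
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
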