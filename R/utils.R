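#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, then restores
#' the previous RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific sub-seed so that independent components of a
# simulation (mask, weights, drift, noise, ...) draw from decoupled streams.
# Keeps results below .Machine$integer.max.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12347L) %% 2147483629
}

# Truncated, edge-renormalised 1-D Gaussian kernel weights for a given sigma
# (in sample units). Returns NULL when sigma is effectively zero.
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 1e-12) return(NULL)
  radius <- max(1L, ceiling(truncate * sigma))
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Convolve each column of a matrix with a 1-D kernel, truncating and
# renormalising the kernel mass at the edges (no implicit zero padding).
smooth_columns_1d <- function(m, w) {
  if (is.null(w)) return(m)
  n <- nrow(m)
  radius <- (length(w) - 1L) / 2L
  out <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    lo <- max(1L, i - radius)
    hi <- min(n, i + radius)
    ww <- w[(lo - i + radius + 1L):(hi - i + radius + 1L)]
    ww <- ww / sum(ww)
    out[i, ] <- ww %*% m[lo:hi, , drop = FALSE]
  }
  out
}

# Smooth a numeric vector with a truncated renormalised Gaussian; fwhm in
# sample units.
smooth_vector_gaussian <- function(v, fwhm) {
  stopifnot(fwhm >= 0)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- gaussian_kernel_1d(sigma)
  if (is.null(w)) return(v)
  drop(smooth_columns_1d(matrix(v, ncol = 1), w))
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
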