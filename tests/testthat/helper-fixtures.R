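# Shared fixtures: small scan matrices and datasets built in code.

# Random timeseries_matrix on a small grid with a full mask.
random_ts <- function(n_scans, grid = c(3, 2, 2), seed = 1,
                      run_boundaries = NULL) {
  set.seed(seed)
  vols <- array(rnorm(prod(grid) * n_scans), c(grid, n_scans))
  apply_mask(vols, mask_volume(array(1, grid)), run_boundaries)
}

# Small PSD linear kernel from random data.
random_linear_kernel <- function(n, d = 12, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n)
  kernel_matrix(tcrossprod(X), "linear")
}

# Tiny quick dataset for pipeline tests. Block ratings over 128-scan runs
# keep task power above the 8-basis DCT cut-off (0.0156 Hz at TR 1.75 s),
# mirroring the full-scale geometry where the high-pass sits far below the
# task band.
quick_config <- function(seed = 1, ...) {
  sim_config(grid_dims = c(8, 8, 4), scans_per_run = 128, n_runs = 2,
             rating_kinds = "block", seed = seed, ...)
}

# Independent projected-gradient solver for min ||Hz - t||^2, 0 <= z <= 1.
# Used as the second-solver oracle for the QP deconvolution.
projected_gradient_box_ls <- function(t_star, H, n_iter = 50000) {
  HtH <- crossprod(H)
  Htt <- drop(crossprod(H, t_star))
  L <- max(eigen(HtH, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / (2 * L)
  z <- rep(0.5, length(t_star))
  for (i in seq_len(n_iter)) {
    g <- 2 * (HtH %*% z - Htt)
    z <- pmin(1, pmax(0, z - step * g))
  }
  z
}

# Direct evaluation of the sparse-Bayes log marginal likelihood
# log N(t | 0, sigma2 I + Phi A^-1 Phi') -- independent of the EM code path.
direct_rvr_evidence <- function(K, t, alpha, sigma2) {
  Phi <- cbind(1, K)
  C <- diag(sigma2, length(t)) + Phi %*% diag(1 / alpha, length(alpha)) %*% t(Phi)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  -0.5 * (length(t) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, t, transpose = TRUE)^2))
}
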