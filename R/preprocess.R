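#' Mask volume
#'
#' A binary 3-D mask restricting analysis to informative voxels (typically
#' gray matter, where task-driven BOLD changes are expected).
#'
#' @param data Numeric/logical 3-D array; nonzero entries mark in-mask voxels.
#' @param voxel_size_mm Length-3 numeric, voxel edge lengths in mm.
#' @return An object of class `mask_volume` with fields `data` (0/1 integer
#'   array), `grid_dims` and `voxel_size_mm`.
#' @export
mask_volume <- function(data, voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(data)) != 3) stop("mask must be a 3-D array")
  m <- array(as.integer(data != 0), dim = dim(data))
  if (sum(m) == 0) stop("mask is empty: no nonzero voxels")
  structure(list(data = m, grid_dims = dim(m),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume: %s grid, %d in-mask voxels (%.1f%%)\n",
              paste(x$grid_dims, collapse = "x"), sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' Threshold a probability map into a binary mask
#'
#' Converts a tissue/region probability map into a `mask_volume` by strict
#' thresholding, `mask = pmap > threshold`. The default 0.3 is the threshold
#' used to binarise warped cytoarchitectonic probability maps for regional
#' feature selection.
#'
#' @param pmap 3-D array with values in \[0, 1\].
#' @param threshold Strict lower cut-off (voxels with `pmap > threshold` kept).
#' @param voxel_size_mm Voxel size passed through to the mask.
#' @return A `mask_volume`.
#' @export
threshold_probability_map <- function(pmap, threshold = 0.3,
                                      voxel_size_mm = c(3, 3, 3)) {
  if (length(dim(pmap)) != 3) stop("pmap must be a 3-D array")
  if (any(pmap < 0 | pmap > 1)) stop("pmap values must lie in [0, 1]")
  m <- pmap > threshold
  if (!any(m)) stop("thresholding produced an empty mask")
  mask_volume(m, voxel_size_mm)
}

#' Scan-by-voxel time-series matrix
#'
#' The `N x D` feature matrix `X`: one row per scan in acquisition order, one
#' column per in-mask voxel. Column order is the fixed raster order of the 3-D
#' grid: x fastest, then y, then z (0-based grid coordinates are recorded in
#' `voxel_index`), so weight maps can be scattered back bit-exactly.
#'
#' @param X Numeric matrix, scans by voxels.
#' @param voxel_index Integer matrix `D x 3` of 0-based grid coordinates per
#'   column.
#' @param grid_dims Source grid dimensions.
#' @param run_boundaries List of integer vectors, the scan indices of each run.
#' @return An object of class `timeseries_matrix`.
#' @export
timeseries_matrix <- function(X, voxel_index, grid_dims,
                              run_boundaries = list(seq_len(nrow(X)))) {
  stop_if_not_finite(X, "time-series matrix")
  stopifnot(nrow(voxel_index) == ncol(X))
  structure(list(X = X, N = nrow(X), D = ncol(X),
                 voxel_index = voxel_index, grid_dims = grid_dims,
                 run_boundaries = run_boundaries),
            class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("timeseries_matrix: N = %d scans x D = %d voxels, %d run(s)\n",
              x$N, x$D, length(x$run_boundaries)))
  invisible(x)
}

#' Extract the masked scan-by-voxel matrix from a 4-D volume series
#'
#' Vectorises each volume over the nonzero voxels of `mask`, in raster order
#' (x fastest, then y, then z).
#'
#' @param volumes 4-D array, grid dims by scans.
#' @param mask A `mask_volume` matching the volume grid.
#' @param run_boundaries Optional list of per-run scan index vectors.
#' @return A `timeseries_matrix`.
#' @export
apply_mask <- function(volumes, mask, run_boundaries = NULL) {
  d <- dim(volumes)
  if (length(d) != 4) stop("volumes must be a 4-D array")
  if (!identical(as.integer(d[1:3]), as.integer(mask$grid_dims)))
    stop("volume grid does not match mask grid")
  idx <- which(mask$data != 0)          # R linear order == x fastest raster
  if (length(idx) == 0) stop("mask is empty")
  n_scan <- d[4]
  flat <- matrix(volumes, nrow = prod(d[1:3]), ncol = n_scan)
  X <- t(flat[idx, , drop = FALSE])
  coords <- arrayInd(idx, mask$grid_dims) - 1L
  if (is.null(run_boundaries)) run_boundaries <- list(seq_len(n_scan))
  timeseries_matrix(X, coords, mask$grid_dims, run_boundaries)
}

#' Scatter a voxel vector or matrix back onto the 3-D grid
#'
#' Inverse of [apply_mask()] for a single map (or one scan): out-of-mask
#' voxels are zero.
#'
#' @param values Numeric vector of length `D` (one value per column of the
#'   source matrix).
#' @param ts A `timeseries_matrix` providing `voxel_index` and `grid_dims`.
#' @return A 3-D array.
#' @export
unmask_map <- function(values, ts) {
  stopifnot(length(values) == ts$D)
  out <- array(0, dim = ts$grid_dims)
  lin <- 1L + ts$voxel_index[, 1] +
    ts$grid_dims[1] * (ts$voxel_index[, 2] + ts$grid_dims[2] * ts$voxel_index[, 3])
  out[lin] <- values
  out
}

#' Build a discrete cosine transform drift basis
#'
#' Constructs the `N x L` orthonormal DCT-II basis `G` whose columns are the
#' `L` lowest-frequency cosines (the constant term, index `l = 0`, is
#' included), plus the residual-forming matrix `R = I - G G^T` that projects a
#' time series onto the complement of the drift subspace. With `per_run`
#' boundaries the basis is block-diagonal, so scans are never mixed across
#' runs.
#'
#' Column `l` is `sqrt(2/N) cos(pi/N (n + 1/2) l)` with the `l = 0` column
#' scaled by `1/sqrt(2)` so that `G^T G = I`. The highest frequency removed by
#' `L` bases over `N` scans at repetition time `tr` seconds is
#' `(L - 1) / (2 N tr)` Hz (see [dct_highpass_cutoff()]).
#'
#' @param N Total number of scans.
#' @param L Number of basis functions (`0 <= L <= N`); `L = 0` yields an empty
#'   basis and `R = I`.
#' @param run_boundaries Optional list of per-run scan index vectors; when
#'   given, an `L`-column DCT is built per run and assembled block-diagonally.
#' @return An object of class `drift_model` with fields `C` (the basis), `L`,
#'   `N` and `R`.
#' @export
build_dct_basis <- function(N, L, run_boundaries = NULL) {
  if (L < 0 || L > N) stop("need 0 <= L <= N")
  if (is.null(run_boundaries)) run_boundaries <- list(seq_len(N))
  stopifnot(sum(lengths(run_boundaries)) == N)
  cols <- list()
  for (ri in seq_along(run_boundaries)) {
    rows <- run_boundaries[[ri]]
    n_run <- length(rows)
    if (L > n_run) stop("L exceeds the number of scans in a run")
    if (L == 0) next
    G <- dct_matrix(n_run, L)
    for (l in seq_len(L)) {
      col <- numeric(N)
      col[rows] <- G[, l]
      cols[[length(cols) + 1L]] <- col
    }
  }
  C <- if (length(cols)) do.call(cbind, cols) else matrix(0, N, 0)
  # orthonormal columns: R = I - CC' directly, which keeps the per-run block
  # structure exact (off-block entries are identically zero)
  structure(list(C = C, L = ncol(C), N = N,
                 R = diag(N) - tcrossprod(C),
                 run_boundaries = run_boundaries),
            class = "drift_model")
}

# Orthonormal DCT-II matrix, n samples, first L columns (l = 0 .. L-1).
dct_matrix <- function(n, L) {
  n_idx <- seq_len(n) - 1
  G <- sapply(seq_len(L) - 1, function(l) {
    v <- sqrt(2 / n) * cos(pi / n * (n_idx + 0.5) * l)
    if (l == 0) v / sqrt(2) else v
  })
  matrix(G, nrow = n)
}

#' Drift model from an arbitrary basis
#'
#' Wraps any drift basis `C` (DCT, polynomial, piecewise ...) together with
#' its residual-forming matrix `R = I - C C^+`, computed through the
#' pseudo-inverse so rank-deficient bases are handled. `R` is symmetric and
#' idempotent and annihilates the columns of `C`.
#'
#' @param C `N x L` numeric basis matrix.
#' @param N Number of scans (defaults to `nrow(C)`).
#' @param run_boundaries Optional run structure carried for bookkeeping.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(C, N = nrow(C), run_boundaries = NULL) {
  C <- as.matrix(C)
  stop_if_not_finite(C, "drift basis")
  structure(list(C = C, L = ncol(C), N = N,
                 R = residual_forming_matrix(C, N),
                 run_boundaries = run_boundaries),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("drift_model: N = %d scans, L = %d basis columns\n", x$N, x$L))
  invisible(x)
}

#' Residual-forming matrix of a drift basis
#'
#' `R = I - C C^+`, the orthogonal projector onto the complement of the
#' column space of `C`. Rank deficiency is absorbed by the Moore-Penrose
#' pseudo-inverse (via SVD).
#'
#' @param C `N x L` basis matrix (`L = 0` allowed).
#' @param N Number of scans.
#' @return `N x N` symmetric idempotent matrix.
#' @export
residual_forming_matrix <- function(C, N = nrow(C)) {
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  stop_if_not_finite(C, "drift basis")
  if (ncol(C) == 0) return(diag(N))
  s <- svd(C)
  keep <- s$d > max(dim(C)) * .Machine$double.eps * max(s$d)
  U <- s$u[, keep, drop = FALSE]
  R <- diag(N) - tcrossprod(U)
  (R + t(R)) / 2
}

#' Remove low-frequency drift from a time-series matrix
#'
#' Applies the residual-forming matrix: `Xbar = R X`. Equivalent, per voxel,
#' to a forward DCT, zeroing of the first `L` coefficients, and inverse DCT.
#'
#' @param ts A `timeseries_matrix`.
#' @param drift A `drift_model` built for the same `N` (and run structure).
#' @return A detrended `timeseries_matrix`.
#' @export
detrend_timeseries <- function(ts, drift) {
  if (drift$N != ts$N) stop("drift model and time series disagree on N")
  out <- ts
  out$X <- drift$R %*% ts$X
  out
}

#' Spatial Gaussian smoothing of a 4-D volume series
#'
#' Separable Gaussian smoothing applied per volume, with
#' `sigma_axis = fwhm_mm / (voxel_size_mm * 2 sqrt(2 log 2))` in voxel units.
#' The kernel is truncated at 4 sigma and renormalised at the array boundary,
#' so a constant image is preserved up to the edges. `fwhm = 0` is the
#' identity.
#'
#' @param volumes 4-D array (x, y, z, scan).
#' @param fwhm_mm Full width at half maximum in mm; scalar or length 3.
#' @param voxel_size_mm Voxel edge lengths in mm; scalar or length 3.
#' @return Smoothed 4-D array of the same shape.
#' @export
smooth_volumes <- function(volumes, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3)) {
  d <- dim(volumes)
  if (length(d) != 4) stop("volumes must be a 4-D array")
  fwhm_mm <- rep_len(fwhm_mm, 3)
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  if (any(fwhm_mm < 0)) stop("fwhm must be non-negative")
  sigma_vox <- fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
  kernels <- lapply(sigma_vox, gaussian_kernel_1d)
  if (all(vapply(kernels, is.null, logical(1)))) return(volumes)
  out <- volumes
  for (s in seq_len(d[4])) {
    vol <- out[, , , s]
    for (ax in 1:3) {
      if (is.null(kernels[[ax]])) next
      vol <- smooth_axis(vol, kernels[[ax]], ax)
    }
    out[, , , s] <- vol
  }
  out
}

# Apply a 1-D kernel along one axis of a 3-D array (truncate/renormalise at
# the boundary). Permutes the target axis to the front, smooths columns, and
# permutes back.
smooth_axis <- function(vol, w, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  m <- smooth_columns_1d(m, w)
  aperm(array(m, dim = dv), inv)
}

#' High-pass cut-off frequency of a DCT drift basis
#'
#' The highest frequency removed when `L` DCT bases (including the constant
#' term) are regressed out of `N` scans sampled every `tr_seconds`:
#' `(L - 1) / (2 N tr)` Hz. For 704 scans at TR 1.75 s and `L = 8` this is
#' 1/352 Hz.
#'
#' @param N Scans per run.
#' @param L Number of DCT bases including the constant.
#' @param tr_seconds Repetition time in seconds.
#' @return Cut-off frequency in Hz.
#' @export
dct_highpass_cutoff <- function(N, L, tr_seconds) {
  stopifnot(L >= 1, N >= L, tr_seconds > 0)
  (L - 1) / (2 * N * tr_seconds)
}
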