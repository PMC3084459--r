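#' Kernel matrix container
#'
#' Holds an `n_rows x n_cols` matrix of pairwise scan similarities together
#' with its kind and provenance flags. Square linear kernels are validated to
#' be symmetric and positive semidefinite.
#'
#' @param values Numeric matrix.
#' @param kind One of `"linear"`, `"rbf"`, `"polynomial"`.
#' @param detrended Logical, whether kernel-space detrending has been applied.
#' @param row_ids,col_ids Optional scan identifiers.
#' @param check Validate symmetry/PSD for square linear kernels.
#' @return An object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind = c("linear", "rbf", "polynomial"),
                          detrended = FALSE, row_ids = NULL, col_ids = NULL,
                          check = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stop_if_not_finite(values, "kernel matrix")
  if (check && kind == "linear" && nrow(values) == ncol(values)) {
    if (max(abs(values - t(values))) > 1e-10 * max(1, max(abs(values))))
      stop("square linear kernel is not symmetric")
    ev <- eigen((values + t(values)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stop("square linear kernel is not positive semidefinite")
  }
  structure(list(values = values, kind = kind, detrended = detrended,
                 row_ids = row_ids, col_ids = col_ids),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d x %d, kind = %s%s\n",
              nrow(x$values), ncol(x$values), x$kind,
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Linear kernel between two scan matrices
#'
#' `K = X_rows X_cols^T`, the Gram matrix of dot products between scans. The
#' two matrices must share the same voxel set (identical `voxel_index`), so
#' that entries are comparable similarities.
#'
#' @param ts_rows,ts_cols `timeseries_matrix` objects; `ts_cols` defaults to
#'   `ts_rows` (the square training kernel).
#' @return A `kernel_matrix` of kind `"linear"`.
#' @export
linear_kernel <- function(ts_rows, ts_cols = ts_rows) {
  if (ts_rows$D != ts_cols$D ||
      !identical(ts_rows$voxel_index, ts_cols$voxel_index))
    stop("voxel mappings of the two scan matrices differ")
  kernel_matrix(tcrossprod(ts_rows$X, ts_cols$X), kind = "linear")
}

#' Detrend a linear kernel in kernel space
#'
#' Applies the residual-forming matrix on both sides: `R^T K R`, which equals
#' the linear kernel of the voxel-space-detrended data without ever touching
#' the `N x D` matrix. Only valid for linear kernels built over the full scan
#' set that `R` indexes; non-linear kernels must be formed *after*
#' detrending.
#'
#' @param K A square linear `kernel_matrix` over train (+ test) scans.
#' @param R Residual-forming matrix (or a `drift_model`).
#' @return The detrended `kernel_matrix`.
#' @export
detrend_kernel <- function(K, R) {
  if (inherits(R, "drift_model")) R <- R$R
  if (K$kind != "linear")
    stop("kernel detrending is only valid for linear kernels (apply before any non-linearity)")
  if (nrow(K$values) != ncol(K$values)) stop("detrend_kernel needs a square kernel")
  if (nrow(R) != nrow(K$values)) stop("R and K disagree on the number of scans")
  out <- K
  out$values <- t(R) %*% K$values %*% R
  out$values <- (out$values + t(out$values)) / 2
  out$detrended <- TRUE
  out
}

#' RBF kernel computed from linear-kernel entries
#'
#' `exp(-gamma ||x_i - x_j||^2)` where the squared distances are recovered
#' from linear-kernel blocks:
#' `||x_i - x_j||^2 = K(x_i,x_i) - 2 K(x_i,x_j) + K(x_j,x_j)`. This lets the
#' RBF kernel be built from a (possibly kernel-detrended) Gram matrix without
#' the voxel data.
#'
#' @param K Linear `kernel_matrix` (cross block, rows by columns).
#' @param gamma Positive RBF width parameter.
#' @param diag_rows,diag_cols Self-similarities `K(x_i, x_i)` for the row and
#'   column scan sets; taken from `diag(K)` when `K` is square and omitted.
#' @return A `kernel_matrix` of kind `"rbf"` (unit diagonal in the square
#'   case).
#' @export
rbf_from_linear <- function(K, gamma, diag_rows = NULL, diag_cols = NULL) {
  if (gamma <= 0) stop("gamma must be > 0")
  V <- K$values
  if (is.null(diag_rows) || is.null(diag_cols)) {
    if (nrow(V) != ncol(V))
      stop("diag_rows and diag_cols are required for non-square kernels")
    diag_rows <- diag_cols <- diag(V)
  }
  d2 <- outer(diag_rows, diag_cols, "+") - 2 * V
  neg <- d2 < 0
  if (any(d2 < -1e-8 * max(1, max(abs(d2)))))
    stop("squared distances are negative beyond numerical tolerance")
  if (any(neg)) {
    d2[neg] <- 0
    warning("small negative squared distances clamped to 0")
  }
  out <- K
  out$values <- exp(-gamma * d2)
  out$kind <- "rbf"
  out
}

#' Polynomial kernel from a linear kernel
#'
#' `(theta + K_ij)^degree`, elementwise.
#'
#' @param K Linear `kernel_matrix`.
#' @param theta Offset, `>= 0`.
#' @param degree Positive integer degree.
#' @return A `kernel_matrix` of kind `"polynomial"`.
#' @export
polynomial_from_linear <- function(K, theta = 1, degree = 2) {
  if (theta < 0) stop("theta must be >= 0")
  if (degree < 1 || degree != round(degree)) stop("degree must be a positive integer")
  out <- K
  out$values <- (theta + K$values)^degree
  stop_if_not_finite(out$values, "polynomial kernel")
  out$kind <- "polynomial"
  out
}

#' Median-heuristic RBF width
#'
#' `gamma = 1 / median(||x_i - x_j||^2)` over distinct training pairs,
#' computed from a linear kernel. A standard default when the width is not
#' cross-validated.
#'
#' @param K Square linear `kernel_matrix` over training scans.
#' @return Positive scalar gamma.
#' @export
rbf_gamma_heuristic <- function(K) {
  V <- K$values
  d2 <- outer(diag(V), diag(V), "+") - 2 * V
  med <- stats::median(d2[upper.tri(d2)])
  if (med <= 0) stop("degenerate scans: median pairwise distance is zero")
  1 / med
}

#' Restrict a scan matrix to a region mask
#'
#' Keeps only the columns whose voxel lies inside `region` — regional feature
#' selection from prior anatomical knowledge (e.g. auditory or visual cortex
#' masks). Downstream kernels are then computed on the restricted matrix.
#'
#' @param ts A `timeseries_matrix`.
#' @param region A `mask_volume` on the same grid.
#' @return The restricted `timeseries_matrix`.
#' @export
apply_region_mask <- function(ts, region) {
  if (!identical(as.integer(region$grid_dims), as.integer(ts$grid_dims)))
    stop("region grid does not match the scan matrix grid")
  lin <- 1L + ts$voxel_index[, 1] +
    ts$grid_dims[1] * (ts$voxel_index[, 2] + ts$grid_dims[2] * ts$voxel_index[, 3])
  keep <- region$data[lin] != 0
  if (!any(keep)) stop("region mask does not intersect the in-mask voxels")
  timeseries_matrix(ts$X[, keep, drop = FALSE],
                    ts$voxel_index[keep, , drop = FALSE],
                    ts$grid_dims, ts$run_boundaries)
}
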