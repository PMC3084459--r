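#' Kernel ridge regression
#'
#' Fits the dual form of ridge regression: `beta = (K + lambda I)^-1 t`,
#' solved by a symmetric (Cholesky) factorisation rather than an explicit
#' inverse. Predictions for a new scan are `t* = sum_i beta_i K(x_i, x*)`.
#' Probabilistically, this is the MAP solution under a Gaussian weight prior
#' with precision `alpha` and noise variance `sigma2`, with
#' `lambda = alpha * sigma2`.
#'
#' @param K Square training `kernel_matrix` (or plain matrix).
#' @param t Numeric target vector of length `N`.
#' @param lambda Ridge penalty, `>= 0`. At `lambda = 0` the kernel must be
#'   invertible.
#' @return An object of class `krr_model` with fields `beta` and `lambda`.
#' @export
fit_krr <- function(K, t, lambda) {
  V <- kernel_values(K)
  N <- nrow(V)
  if (ncol(V) != N) stop("training kernel must be square")
  if (length(t) != N) stop("target length does not match kernel size")
  if (lambda < 0) stop("lambda must be >= 0")
  beta <- sym_solve(V + diag(lambda, N), t,
                    context = if (lambda == 0)
                      "singular kernel at lambda = 0; use lambda > 0" else NULL)
  structure(list(beta = as.numeric(beta), lambda = lambda, N = N),
            class = "krr_model")
}

#' @export
print.krr_model <- function(x, ...) {
  cat(sprintf("krr_model: N = %d dual weights, lambda = %g\n", x$N, x$lambda))
  invisible(x)
}

kernel_values <- function(K) {
  if (inherits(K, "kernel_matrix")) K$values else as.matrix(K)
}

# Symmetric positive (semi)definite solve with a jitter fallback: on Cholesky
# failure, add 1e-10 * trace/N to the diagonal and retry once before erroring.
sym_solve <- function(A, b, context = NULL) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * sum(diag(A)) / nrow(A)
    ch <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (is.null(ch))
      stop(if (!is.null(context)) context else "symmetric solve failed", call. = FALSE)
  }
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Predict from a fitted kernel regression model
#'
#' For KRR, `t* = K_test_train beta`. For RVR, a leading column of ones is
#' appended internally and `t* = Phi* mu`; only columns in the relevant set
#' contribute.
#'
#' @param model A `krr_model` or `rvr_model`.
#' @param K_test_train `kernel_matrix` (or matrix) of test rows by training
#'   columns, columns ordered as the training scans.
#' @return Numeric vector of predictions.
#' @export
predict_kernel_model <- function(model, K_test_train) {
  V <- kernel_values(K_test_train)
  if (inherits(model, "krr_model")) {
    if (ncol(V) != model$N) stop("kernel column count does not match training scans")
    return(drop(V %*% model$beta))
  }
  if (inherits(model, "rvr_model")) {
    if (ncol(V) != model$N) stop("kernel column count does not match training scans")
    Phi_star <- cbind(1, V)
    return(drop(Phi_star %*% model$mu))
  }
  stop("model must be a krr_model or rvr_model")
}

#' Relevance vector regression with automatic relevance determination
#'
#' Sparse Bayesian regression on the design `Phi = [1, K]` (bias column plus
#' kernel columns). Each weight has an independent zero-mean Gaussian prior
#' with precision `alpha_i`; type-II maximum likelihood iterates
#' \itemize{
#'   \item `Sigma = (sigma^-2 Phi^T Phi + A)^-1`, `mu = sigma^-2 Sigma Phi^T t`
#'   \item `gamma_i = 1 - alpha_i Sigma_ii`, `alpha_i <- gamma_i / mu_i^2`
#'   \item `sigma2 <- ||t - Phi mu||^2 / (N - sum gamma_i)`
#' }
#' until the log marginal likelihood stabilises. Precisions that diverge are
#' pruned from the active set (automatic relevance determination); the
#' surviving kernel columns are the relevance vectors.
#'
#' @param K Square training `kernel_matrix` (or matrix).
#' @param t Target vector.
#' @param tol Convergence threshold on the change in log-evidence.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   flagged `converged = FALSE`.
#' @param prune_threshold Absolute alpha above which a weight is pruned; a
#'   relative rule `alpha_i > 1e9 * mean(alpha_active)` is applied as well.
#' @param alpha_init,sigma2_init Initial precisions and noise variance
#'   (defaults `1/N^2` and `0.1 var(t)`).
#' @return An object of class `rvr_model`: posterior mean `mu` (length
#'   `N + 1`, index 1 = bias; pruned entries exactly 0), `alpha`, `sigma2`,
#'   `relevant_idx` (1-based into `mu`), `log_evidence` trace and `converged`.
#' @export
fit_rvr <- function(K, t, tol = 1e-6, max_iter = 1000,
                    prune_threshold = 1e12, alpha_init = NULL,
                    sigma2_init = NULL) {
  V <- kernel_values(K)
  N <- nrow(V)
  if (ncol(V) != N) stop("training kernel must be square")
  if (N < 3) stop("RVR needs at least 3 training scans")
  if (length(t) != N) stop("target length does not match kernel size")
  Phi_full <- cbind(1, V)
  M <- N + 1L
  active <- seq_len(M)
  alpha <- rep(if (is.null(alpha_init)) 1 / N^2 else alpha_init, M)
  sigma2 <- if (is.null(sigma2_init)) 0.1 * stats::var(t) else sigma2_init
  if (sigma2 <= 0) sigma2 <- 1e-6
  sigma2_floor <- 1e-12 * max(stats::var(t), .Machine$double.eps)
  ev_trace <- numeric(0)
  converged <- FALSE
  mu_a <- NULL; Sigma_a <- NULL
  for (iter in seq_len(max_iter)) {
    Phi <- Phi_full[, active, drop = FALSE]
    A <- diag(alpha[active], length(active))
    H <- crossprod(Phi) / sigma2 + A
    ch <- chol(H)
    Sigma_a <- chol2inv(ch)
    mu_a <- drop(Sigma_a %*% crossprod(Phi, t)) / sigma2
    # log marginal likelihood of the current (alpha, sigma2); the quadratic
    # form uses the residual identity t'C^-1 t = ||t - Phi mu||^2 / sigma2 +
    # mu'A mu, which avoids catastrophic cancellation at small sigma2
    logdetC <- N * log(sigma2) - sum(log(alpha[active])) +
      2 * sum(log(diag(ch)))
    resid0 <- t - drop(Phi %*% mu_a)
    quad <- sum(resid0^2) / sigma2 + sum(alpha[active] * mu_a^2)
    ev <- -0.5 * (N * log(2 * pi) + logdetC + quad)
    ev_trace <- c(ev_trace, ev)
    if (iter > 1 && abs(ev - ev_trace[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    gamma <- 1 - alpha[active] * diag(Sigma_a)
    denom <- N - sum(gamma)
    if (denom <= 0) stop("effective degrees of freedom exhausted (N - sum(gamma) <= 0)")
    alpha_new <- gamma / pmax(mu_a^2, .Machine$double.xmin)
    alpha[active] <- alpha_new
    sigma2 <- sum(resid0^2) / denom
    if (!is.finite(sigma2) || sigma2 < sigma2_floor) sigma2 <- sigma2_floor
    keep <- alpha[active] < prune_threshold &
      alpha[active] < 1e9 * mean(alpha[active])
    if (!any(keep)) keep[which.min(alpha[active])] <- TRUE
    active <- active[keep]
  }
  mu <- numeric(M)
  mu[active] <- mu_a
  structure(list(mu = mu, alpha = alpha, sigma2 = sigma2,
                 relevant_idx = active, N = N,
                 log_evidence = ev_trace, converged = converged),
            class = "rvr_model")
}

#' @export
print.rvr_model <- function(x, ...) {
  cat(sprintf(
    "rvr_model: %d/%d relevance vectors (%.1f%%), sigma2 = %.4g, %sconverged\n",
    length(setdiff(x$relevant_idx, 1L)), x$N, 100 * sparsity(x), x$sigma2,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Sparsity of a fitted relevance vector model
#'
#' Fraction of training scans retained as relevance vectors (bias excluded):
#' `|relevant kernel columns| / N`.
#'
#' @param model An `rvr_model`.
#' @return A number in \[0, 1\].
#' @export
sparsity <- function(model) {
  stopifnot(inherits(model, "rvr_model"))
  length(setdiff(model$relevant_idx, 1L)) / model$N
}

#' Gaussian-process evidence optimisation of kernel hyperparameters
#'
#' Maximises the marginal likelihood of the targets under
#' `t ~ N(0, C)`, `C = theta1 I + theta2 K` (optionally
#' `+ theta3 11^T`, a constant covariance term accounting for a target
#' offset). The implied ridge penalty is `lambda = theta1 / theta2`.
#' Optimisation runs in log-theta (positivity by construction) with BFGS from
#' three seeded random restarts.
#'
#' @param K Square PSD `kernel_matrix` (or matrix).
#' @param t Target vector; an all-zero target is degenerate and errors.
#' @param include_constant Add the `theta3` constant term.
#' @param n_restarts Number of random restarts.
#' @param seed Seed for the restart draws.
#' @return An object of class `evidence_hyperparams`: `theta1`, `theta2`,
#'   `theta3` (0 when excluded), `lambda`, `log_evidence`, `converged`.
#' @export
optimize_evidence <- function(K, t, include_constant = FALSE,
                              n_restarts = 3, seed = 1) {
  V <- kernel_values(K)
  N <- nrow(V)
  if (ncol(V) != N) stop("kernel must be square")
  if (length(t) != N) stop("target length does not match kernel size")
  if (all(t == 0)) stop("degenerate target: t is identically zero")
  # Shared eigenbasis: C = theta1 I + theta2 K is diagonal in K's eigenbasis,
  # making each evidence evaluation O(N) after one decomposition.
  es <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam_k <- pmax(es$values, 0)
  tU <- drop(crossprod(es$vectors, t))
  ones_U <- drop(crossprod(es$vectors, rep(1, N)))
  neg_log_ev <- function(lp) {
    th <- exp(lp)
    if (any(!is.finite(th))) return(1e10)
    if (!include_constant) {
      d <- th[1] + th[2] * lam_k
      if (any(d <= 0)) return(1e10)
      val <- 0.5 * (N * log(2 * pi) + sum(log(d)) + sum(tU^2 / d))
    } else {
      # rank-one update of the diagonal form: C = D + th3 * 1 1^T
      d <- th[1] + th[2] * lam_k
      if (any(d <= 0)) return(1e10)
      s <- 1 + th[3] * sum(ones_U^2 / d)
      a <- sum(ones_U * tU / d)
      quad <- sum(tU^2 / d) - th[3] * a^2 / s
      logdet <- sum(log(d)) + log(s)
      val <- 0.5 * (N * log(2 * pi) + logdet + quad)
    }
    if (!is.finite(val)) 1e10 else val
  }
  n_par <- if (include_constant) 3L else 2L
  scale0 <- stats::var(t)
  kscale <- mean(diag(V)) + 1e-12
  starts <- with_seed(seed, {
    s0 <- log(c(0.5 * scale0, 0.5 * scale0 / kscale,
                if (include_constant) 0.1 * scale0))
    lapply(seq_len(max(1, n_restarts)), function(i) {
      if (i == 1) s0 else s0 + stats::rnorm(n_par, sd = 2)
    })
  })
  best <- NULL
  ok <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, neg_log_ev, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (!is.null(fit) && fit$convergence == 0) ok <- TRUE
  }
  if (is.null(best)) stop("evidence optimisation failed from all restarts")
  th <- exp(best$par)
  structure(list(theta1 = th[1], theta2 = th[2],
                 theta3 = if (include_constant) th[3] else 0,
                 lambda = th[1] / th[2],
                 log_evidence = -best$value,
                 converged = ok && best$convergence == 0),
            class = "evidence_hyperparams")
}

#' @export
print.evidence_hyperparams <- function(x, ...) {
  cat(sprintf(
    "evidence_hyperparams: theta1 = %.4g, theta2 = %.4g, theta3 = %.4g, lambda = %.4g (logL = %.3f)\n",
    x$theta1, x$theta2, x$theta3, x$lambda, x$log_evidence))
  invisible(x)
}

#' Reconstruct the voxel-space weight map of a kernel model
#'
#' For a linear kernel the dual solution corresponds to the primal weight
#' vector `w = X^T R beta` (with `R = I` if the kernel was not detrended),
#' scattered back onto the 3-D grid. The prediction identity
#' `t*_j = w^T (R x_j)` holds for every scan. For RVR pass `beta = mu[-1]`
#' (bias excluded).
#'
#' @param ts Training `timeseries_matrix` (the matrix the kernel was built
#'   from, before detrending).
#' @param beta Dual weight vector of length `N`, or a fitted `krr_model` /
#'   `rvr_model`.
#' @param R Residual-forming matrix used for detrending, or `NULL` for
#'   identity.
#' @return List with `map` (3-D array on the source grid) and `w` (the
#'   in-mask weight vector).
#' @export
weight_map <- function(ts, beta, R = NULL) {
  if (inherits(beta, "krr_model")) beta <- beta$beta
  if (inherits(beta, "rvr_model")) beta <- beta$mu[-1]
  if (length(beta) != ts$N) stop("beta length does not match the scan count")
  if (inherits(R, "drift_model")) R <- R$R
  v <- if (is.null(R)) beta else drop(R %*% beta)
  w <- drop(crossprod(ts$X, v))
  list(map = unmask_map(w, ts), w = w)
}
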