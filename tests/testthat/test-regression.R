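test_that("KRR closed forms: identity kernel and lambda dominance", {
  t <- c(1, -2, 0.5)
  m <- fit_krr(diag(3), t, 1)
  expect_equal(m$beta, t / 2, tolerance = 1e-12)
  K <- random_linear_kernel(8, seed = 1)
  big <- fit_krr(K, rnorm(8), 1e12)
  expect_lte(sqrt(sum(big$beta^2)),
             sqrt(sum(rnorm(8)^2)) / 1e12 * (1 + 1e-6) + 1e-10)
  expect_error(fit_krr(matrix(0, 3, 3), t, 0), "lambda")
})

test_that("dual KRR equals primal ridge, and the MAP form with lambda = alpha sigma2", {
  set.seed(21)
  N <- 6; D <- 3
  X <- matrix(rnorm(N * D), N)
  t <- rnorm(N)
  Xs <- matrix(rnorm(2 * D), 2)            # test scans
  alpha <- 1.7; sigma2 <- 0.4
  lambda <- alpha * sigma2
  # primal ridge oracle (normal equations in voxel space)
  w <- solve(crossprod(X) + diag(lambda, D), crossprod(X, t))
  m <- fit_krr(tcrossprod(X), t, lambda)
  expect_equal(drop(Xs %*% w),
               predict_kernel_model(m, Xs %*% t(X)), tolerance = 1e-8)
  # MAP weights under the Gaussian prior coincide with ridge
  w_map <- solve(crossprod(X) / sigma2 + diag(alpha, D), crossprod(X, t)) / sigma2
  expect_equal(drop(w), drop(w_map), tolerance = 1e-8)
})

test_that("KRR prediction interpolates at lambda 0 and matches the summation oracle", {
  K <- random_linear_kernel(6, d = 20, seed = 4)
  t <- rnorm(6)
  m0 <- fit_krr(K, t, 0)
  expect_equal(predict_kernel_model(m0, K$values[3, , drop = FALSE]), t[3],
               tolerance = 1e-6)
  Kte <- K$values[1:2, ]
  pred <- predict_kernel_model(m0, Kte)
  oracle <- sapply(1:2, function(j) sum(m0$beta * Kte[j, ]))
  expect_equal(pred, oracle, tolerance = 1e-12)
  expect_error(predict_kernel_model(m0, K$values[, 1:3]), "column")
})

test_that("KRR dual weights are continuous in lambda", {
  K <- random_linear_kernel(10, seed = 6)
  t <- rnorm(10)
  lam <- 5
  gaps <- sapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    sqrt(sum((fit_krr(K, t, lam)$beta - fit_krr(K, t, lam + eps)$beta)^2))
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-6)
})

test_that("RVR recovers a constructed sparse truth with monotone evidence", {
  set.seed(2)
  N <- 50
  K <- tcrossprod(matrix(rnorm(N * 10), N))
  K <- K / mean(diag(K))
  t <- 2 * K[, 7] + 0.5                      # one kernel column + bias
  m <- fit_rvr(K, t)
  expect_true(all(m$relevant_idx %in% c(1L, 8L)))   # bias + column 7
  expect_lt(max(abs(t - predict_kernel_model(m, K))), 1e-6)
  expect_lte(sparsity(m), 0.1)
  # pruned weights are exactly zero; precisions positive
  expect_true(all(m$mu[-m$relevant_idx] == 0))
  expect_true(all(m$alpha > 0) && m$sigma2 > 0)
  # noisy problem: evidence non-decreasing along the EM trace
  t2 <- 2 * K[, 7] + 0.5 + rnorm(N, sd = 0.2)
  m2 <- fit_rvr(K, t2)
  expect_true(m2$converged)
  expect_true(all(diff(m2$log_evidence) > -1e-8))
})

test_that("RVR EM fixed point matches brute-force evidence maximisation at N = 5", {
  set.seed(14)
  N <- 5
  K <- tcrossprod(matrix(rnorm(N * 3), N))
  K <- K / mean(diag(K))
  t <- K[, 2] - 0.5 * K[, 4] + rnorm(N, sd = 0.3)
  m <- fit_rvr(K, t)
  ev_em <- direct_rvr_evidence(K, t, m$alpha, m$sigma2)
  # independent grid + simplex search over (log alpha, log sigma2)
  obj <- function(p) {
    v <- -direct_rvr_evidence(K, t, exp(pmin(p[1:(N + 1)], 60)),
                              exp(max(p[N + 2], -60)))
    if (is.finite(v)) v else 1e10
  }
  best <- Inf
  for (a0 in c(-4, 0, 4)) for (s0 in c(-3, 0)) {
    st <- c(rep(a0, N + 1), s0)
    fit <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  expect_lt(abs(-best - ev_em), 1e-4)
})

test_that("RVR predictions with everything pruned reduce to the bias", {
  m <- structure(list(mu = c(2.5, numeric(4)), alpha = rep(1, 5), sigma2 = 1,
                      relevant_idx = 1L, N = 4L, log_evidence = 0,
                      converged = TRUE), class = "rvr_model")
  expect_equal(predict_kernel_model(m, matrix(rnorm(12), 3)), rep(2.5, 3))
  expect_equal(sparsity(m), 0)
})

test_that("evidence optimisation recovers the noise/signal ratio and favours the constant term", {
  set.seed(31)
  N <- 120
  K <- tcrossprod(matrix(rnorm(N * 25), N)) / 25
  L <- chol(2 * diag(N) + 3 * K)
  t <- drop(crossprod(L, rnorm(N)))
  hp <- optimize_evidence(K, t, seed = 5)
  expect_gt(hp$lambda, 0.2); expect_lt(hp$lambda, 2)   # true ratio 2/3
  # a large target offset is absorbed by the constant covariance term
  t_off <- t + 20
  hp0 <- optimize_evidence(K, t_off, include_constant = FALSE, seed = 5)
  hp1 <- optimize_evidence(K, t_off, include_constant = TRUE, seed = 5)
  expect_gt(hp1$log_evidence, hp0$log_evidence)
  expect_error(optimize_evidence(K, numeric(N)), "degenerate")
})

test_that("weight maps satisfy the prediction identity and localise the source", {
  cfg <- quick_config(seed = 2, noise_sd = 0.5)
  ds <- generate_dataset(cfg)
  ts <- apply_mask(ds$volumes, ds$gm_mask, ds$run_boundaries)
  drift <- build_dct_basis(ts$N, 8, ts$run_boundaries)
  K <- detrend_kernel(linear_kernel(ts), drift)
  target <- ds$convolved_ratings[[1]]
  m <- fit_krr(K, target, 100)
  wm <- weight_map(ts, m, drift)
  # t*_j = w' (R x_j) for every training scan
  pred_w <- drop((drift$R %*% ts$X) %*% wm$w)
  pred_k <- predict_kernel_model(m, K$values)
  expect_equal(pred_w, pred_k, tolerance = 1e-8)
  # beta = e_i with R = I picks out scan i's voxel pattern
  e2 <- numeric(ts$N); e2[2] <- 1
  expect_equal(weight_map(ts, e2)$w, ts$X[2, ], tolerance = 1e-12)
  # map is zero off-mask and peaks inside the true blob support
  expect_true(all(wm$map[ds$gm_mask$data == 0] == 0))
})

test_that("weight-map peak falls inside the true active blob across seeds", {
  hits <- sapply(1:20, function(seed) {
    cfg <- quick_config(seed = seed, noise_sd = 1)
    ds <- generate_dataset(cfg)
    ts <- apply_mask(ds$volumes, ds$gm_mask, ds$run_boundaries)
    drift <- build_dct_basis(ts$N, 8, ts$run_boundaries)
    K <- detrend_kernel(linear_kernel(ts), drift)
    m <- fit_krr(K, ds$convolved_ratings[[1]], 100)
    wm <- weight_map(ts, m, drift)
    peak <- which.max(abs(wm$map))
    ds$true_weight_maps[[1]][peak] > 0.01
  })
  expect_gte(sum(hits), 18)
})

test_that("cross-validated correlation plateaus over mid-range regularisation", {
  cfg <- sim_config(grid_dims = c(8, 8, 4), scans_per_run = 128, n_runs = 2,
                    rating_kinds = "block", noise_sd = 0.8, seed = 12)
  ds <- generate_dataset(cfg)
  rs <- sapply(10^(2:5), function(lam) {
    tab <- cross_validate(ds, pipeline_config(model = list(lambda = lam)))
    mean(tab$pearson_r)
  })
  expect_lt(max(rs) - min(rs), 0.05)
})
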