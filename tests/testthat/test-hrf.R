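test_that("canonical HRF starts at zero, peaks near 5 s, decays by 32 s", {
  h <- canonical_hrf(0.01)                    # dense sampling
  tt <- seq(0, 32, by = 0.01)
  expect_lt(abs(h$samples[1]), 1e-3)          # relative to unit peak
  expect_equal(max(h$samples), 1)
  peak_t <- tt[which.max(h$samples)]
  expect_gte(peak_t, 4.5); expect_lte(peak_t, 5.5)
  expect_lt(abs(h$samples[length(h$samples)]), 0.02)
  expect_error(canonical_hrf(1.75, peak_disp = 0), "dispersion")
})

test_that("Toeplitz convolution matches the direct causal loop", {
  h <- canonical_hrf(1.75)
  N <- 50
  H <- convolution_matrix(h, N)
  expect_true(all(H[upper.tri(H)] == 0))
  expect_equal(H[, 1], c(h$samples, numeric(N - length(h$samples))))
  z <- numeric(N); z[1] <- 1
  expect_equal(drop(H %*% z), H[, 1])          # impulse response
  set.seed(3)
  z <- runif(N)
  direct <- sapply(seq_len(N), function(n)
    sum(h$samples[seq_len(min(n, length(h$samples)))] *
          z[n - seq_len(min(n, length(h$samples))) + 1L]))
  expect_equal(drop(H %*% z), direct, tolerance = 1e-12)
  expect_equal(drop(H %*% numeric(N)), numeric(N))
})

test_that("convolution is causal: later inputs never affect earlier outputs", {
  H <- convolution_matrix(canonical_hrf(1.75), 30)
  z <- runif(30)
  base <- drop(H %*% z)
  z2 <- z; z2[20] <- z2[20] + 5
  pert <- drop(H %*% z2)
  expect_equal(pert[1:19], base[1:19], tolerance = 1e-14)
})

test_that("constrained deconvolution attains the box-constrained optimum", {
  h <- canonical_hrf(1.75)
  N <- 40
  H <- convolution_matrix(h, N)
  # feasible zero-residual truth is recovered
  set.seed(5)
  z0 <- as.numeric(runif(N) > 0.6)
  t_star <- drop(H %*% z0)
  z <- deconvolve_constrained(t_star, H)
  expect_lt(sum((H %*% z - t_star)^2), 1e-8)
  expect_gte(min(z), -1e-9); expect_lte(max(z), 1 + 1e-9)
  # second-solver oracle on an infeasible random target
  t_rand <- rnorm(N)
  z1 <- deconvolve_constrained(t_rand, H)
  z2 <- projected_gradient_box_ls(t_rand, H)
  f <- function(z) sum((H %*% z - t_rand)^2)
  expect_lt(abs(f(z1) - f(z2)), 1e-6)
  # the constrained optimum dominates the clipped unconstrained solution
  z_ls <- pmin(1, pmax(0, solve(crossprod(H) + diag(1e-10, N),
                                crossprod(H, t_rand))))
  expect_lte(f(z1), f(z_ls) + 1e-10)
  # strongly negative targets clamp to the lower boundary
  expect_equal(deconvolve_constrained(rep(-50, N), H), numeric(N),
               tolerance = 1e-6)
})

test_that("re-convolution and temporal smoothing behave at the edges", {
  H <- convolution_matrix(canonical_hrf(1.75), 30)
  z <- runif(30)
  expect_equal(reconvolve_smooth(z, H, fwhm_tr = 0), drop(H %*% z))
  # constant series is untouched by renormalised smoothing
  expect_equal(smooth_vector_gaussian(rep(2, 20), 3), rep(2, 20),
               tolerance = 1e-9)
})

test_that("deconvolve-reconvolve-smooth improves noisy predictions", {
  h <- canonical_hrf(1.75)
  N <- 96
  H <- convolution_matrix(h, N)
  wins <- sapply(1:20, function(seed) {
    set.seed(seed)
    z0 <- generate_rating("block", N, list(block_len = 12), seed = seed)
    t_true <- drop(H %*% z0)
    pred <- t_true + rnorm(N, sd = 0.6 * sd(t_true))
    z <- deconvolve_constrained(pred, H)
    furnished <- reconvolve_smooth(z, H, 3)
    pearson_r(furnished, t_true) > pearson_r(pred, t_true)
  })
  expect_gte(sum(wins), 15)
})

test_that("temporal shifting round-trips away from the edges", {
  v <- rnorm(40)
  expect_identical(temporal_shift(v, 0), v)
  for (k in c(-3, 2)) {
    rt <- inverse_shift(temporal_shift(v, k), k)
    inner <- (abs(k) + 1):(40 - abs(k))
    expect_equal(rt[inner], v[inner])
  }
  expect_error(temporal_shift(v, 10), "N/4")
})

test_that("training-target shift recovers a leading hemodynamic response", {
  # signal in the volumes leads the scored (canonically convolved) target by
  # one scan; shifting the training target earlier should win
  wins <- sapply(1:20, function(seed) {
    cfg <- quick_config(seed = seed, noise_sd = 1, effect_amplitude = 0)
    ds <- generate_dataset(cfg)
    conv <- ds$convolved_ratings[[1]]
    lead <- temporal_shift(conv, -1)
    sig <- as.numeric(ds$true_weight_maps[[1]]) %o% lead
    ds$volumes <- ds$volumes + array(3 * sig, dim(ds$volumes))
    r_at <- function(k) {
      tab <- cross_validate(ds, pipeline_config(
        model = list(lambda = 10),
        postprocessing = list(shift_k = k)))
      mean(tab$pearson_r)
    }
    r_at(-1) > r_at(0)
  })
  expect_gte(sum(wins), 15)
})

test_that("spike templates average to the common shape", {
  tmpl <- krfmri:::default_spike_template(1.75)
  r1 <- numeric(60); r1[5:(4 + length(tmpl))] <- tmpl
  r2 <- numeric(60); r2[30:(29 + length(tmpl))] <- tmpl
  est <- build_spike_template(list(r1, r2))
  expect_equal(est, tmpl, tolerance = 1e-12)
  # single spike: the spike itself, peak-normalised
  est1 <- build_spike_template(r1 * 0.5)
  expect_equal(est1, tmpl, tolerance = 1e-12)
  expect_error(build_spike_template(numeric(20)), "no spikes")
  # noisy events: averaging shrinks the error like 3 sd / sqrt(n)
  set.seed(6)
  shape <- tmpl[1:8]
  n_ev <- 100; sd_n <- 0.05
  ratings <- lapply(seq_len(n_ev), function(i) {
    r <- numeric(20); r[3:10] <- pmax(shape + rnorm(8, sd = sd_n), 1e-6); r
  })
  est2 <- build_spike_template(ratings, threshold = 0)
  expect_lt(max(abs(est2 - shape / max(shape))), 3 * sd_n / sqrt(n_ev) + 0.02)
})

test_that("match filtering recovers event lags and reconstructs the rating", {
  set.seed(10)
  tmpl <- krfmri:::default_spike_template(1.75)
  z <- generate_rating("spikes", 350, list(k = 7), seed = 17)
  true_lags <- attr(match_filter_insert(z, tmpl, 7), "lags")
  # exact self-match: noise-free recovery of all lags
  rec <- match_filter_insert(z, tmpl, 7)
  expect_equal(attr(rec, "lags"), true_lags)
  expect_equal(rec, z, ignore_attr = TRUE, tolerance = 1e-12)
  # near-perfect reconstruction lifts an r ~ 0.8 prediction
  lifts <- sapply(1:20, function(seed) {
    set.seed(seed)
    noisy <- z + rnorm(length(z), sd = sd(z) / 1.35)
    r0 <- pearson_r(noisy, z)
    r1 <- pearson_r(match_filter_insert(noisy, tmpl, 7), z)
    c(r0 = r0, r1 = r1)
  })
  expect_lt(abs(mean(lifts["r0", ]) - 0.8), 0.1)
  expect_gte(sum(lifts["r1", ] > 0.95), 15)
  expect_error(match_filter_insert(z[1:40], tmpl, 7), "admissible")
  expect_error(match_filter_insert(z[seq_len(length(tmpl) - 1)], tmpl, 7),
               "shorter")
})
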