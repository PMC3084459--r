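#' Simulation configuration
#'
#' Settings for the synthetic fMRI generator, which emulates a multi-run
#' virtual-reality decoding session: gray-matter-restricted rating-driven
#' signal, slow scanner drift, and white measurement noise. Defaults are the
#' desk-scale study conditions: a 16 x 16 x 8 grid, 3 runs of 128 scans at
#' TR 1.75 s, drift components below 0.0015 Hz. The full acquisition-scale
#' geometry (64 x 64 x 34, 704 scans per run) is obtained by passing those
#' values explicitly.
#'
#' @param grid_dims Three positive integers, voxels per axis.
#' @param voxel_size_mm Three positive reals (mm).
#' @param n_runs,scans_per_run Run structure; `scans_per_run >= 2`.
#' @param tr_seconds Repetition time (s).
#' @param rating_kinds Character vector drawn from `"block"`, `"spikes"`,
#'   `"continuous"`; one rating is generated per entry.
#' @param effect_amplitude Signal units per unit of convolved rating.
#' @param n_active_blobs Gaussian activation blobs per rating.
#' @param drift_amplitude Amplitude of the low-frequency drift field.
#' @param drift_max_freq_hz Highest drift frequency (Hz); must respect the
#'   Nyquist limit `1 / (2 TR)`.
#' @param noise_sd Standard deviation of iid Gaussian measurement noise.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_dims = c(16, 16, 8), voxel_size_mm = c(3, 3, 3),
                       n_runs = 3, scans_per_run = 128, tr_seconds = 1.75,
                       rating_kinds = c("continuous", "block"),
                       effect_amplitude = 3, n_active_blobs = 2,
                       drift_amplitude = 10, drift_max_freq_hz = 0.0015,
                       noise_sd = 1, seed = 1) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            length(voxel_size_mm) == 3, all(voxel_size_mm > 0),
            n_runs >= 1, scans_per_run >= 2, tr_seconds > 0,
            effect_amplitude >= 0, n_active_blobs >= 1,
            drift_amplitude >= 0, noise_sd >= 0)
  if (!all(rating_kinds %in% c("block", "spikes", "continuous")))
    stop("rating_kinds must be drawn from block, spikes, continuous")
  if (drift_max_freq_hz <= 0 || drift_max_freq_hz >= 1 / (2 * tr_seconds))
    stop("drift_max_freq_hz must lie in (0, 1/(2 TR))")
  structure(list(grid_dims = as.integer(grid_dims),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_runs = as.integer(n_runs),
                 scans_per_run = as.integer(scans_per_run),
                 tr_seconds = tr_seconds,
                 n_ratings = length(rating_kinds),
                 rating_kinds = rating_kinds,
                 effect_amplitude = effect_amplitude,
                 n_active_blobs = as.integer(n_active_blobs),
                 drift_amplitude = drift_amplitude,
                 drift_max_freq_hz = drift_max_freq_hz,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s grid @ %s mm, %d runs x %d scans, TR %.3g s\n  ratings: %s; effect %g, drift %g (<= %g Hz), noise sd %g, seed %d\n",
    paste(x$grid_dims, collapse = "x"),
    paste(x$voxel_size_mm, collapse = "x"),
    x$n_runs, x$scans_per_run, x$tr_seconds,
    paste(x$rating_kinds, collapse = ", "), x$effect_amplitude,
    x$drift_amplitude, x$drift_max_freq_hz, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a raw rating time course
#'
#' Raw (pre-convolution) ratings in \[0, 1\]:
#' \itemize{
#'   \item `block`: alternating on/off blocks of `block_len` scans with a
#'     random circular phase (binary values);
#'   \item `spikes`: `k` non-overlapping copies of a fixed event template on
#'     a zero baseline (default template: the peak-normalised hemodynamic
#'     response to a 3-scan boxcar), at random non-overlapping onsets;
#'   \item `continuous`: a smoothed bounded random walk rescaled to \[0, 1\].
#' }
#'
#' @param kind `"block"`, `"spikes"` or `"continuous"`.
#' @param n_scans Number of scans (`>= 2`).
#' @param params Kind-specific settings: `block_len` (block), `k` event count
#'   and `template` vector (spikes), `step_sd` and `smooth_fwhm`
#'   (continuous).
#' @param seed Integer seed.
#' @param tr_seconds TR used for the default spike template.
#' @return Numeric vector of length `n_scans` with values in \[0, 1\].
#' @export
generate_rating <- function(kind = c("block", "spikes", "continuous"),
                            n_scans, params = list(), seed = 1,
                            tr_seconds = 1.75) {
  kind <- match.arg(kind)
  if (n_scans < 2) stop("n_scans must be >= 2")
  with_seed(seed, switch(kind,
    block = {
      block_len <- params$block_len %||% 16L
      base <- rep(rep(c(1, 0), each = block_len), length.out = n_scans)
      shift <- sample.int(2L * block_len, 1L) - 1L
      base[((seq_len(n_scans) - 1L + shift) %% n_scans) + 1L]
    },
    spikes = {
      k <- params$k %||% 7L
      tmpl <- params$template %||% default_spike_template(tr_seconds)
      m <- length(tmpl)
      if (k * m > n_scans)
        stop(sprintf("cannot fit %d non-overlapping events of %d scans into %d scans",
                     k, m, n_scans))
      slack <- n_scans - k * m
      cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
      onsets <- cuts + (seq_len(k) - 1L) * m + 1L
      out <- numeric(n_scans)
      for (s in onsets) out[s:(s + m - 1L)] <- tmpl
      out
    },
    continuous = {
      step_sd <- params$step_sd %||% 0.1
      fwhm <- params$smooth_fwhm %||% 8
      walk <- cumsum(stats::rnorm(n_scans, sd = step_sd))
      walk <- smooth_vector_gaussian(walk, fwhm)
      rng <- range(walk)
      if (diff(rng) < 1e-12) rep(0.5, n_scans)
      else (walk - rng[1]) / diff(rng)
    }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Peak-normalised hemodynamic response to a 3-scan boxcar: the event shape
# used for spike-type ratings. The positive main lobe is kept (undershoot
# clipped at zero) and flanking zeros trimmed so every template sample is
# supra-threshold.
default_spike_template <- function(tr_seconds = 1.75) {
  hrf <- canonical_hrf(tr_seconds)
  box <- c(1, 1, 1)
  v <- stats::convolve(c(box, numeric(length(hrf$samples))),
                       rev(hrf$samples), type = "open")
  v <- pmax(v[seq_len(length(hrf$samples) + 3L)], 0)
  nz <- which(v > 1e-10 * max(v))
  v <- v[min(nz):max(nz)]
  v[v <= 0] <- 1e-8 * max(v)     # keep the segment contiguous when detected
  v / max(v)
}

#' Generate a synthetic multi-run fMRI dataset with known ground truth
#'
#' Builds 4-D volumes as
#' `baseline + drift + sum_r effect_amplitude * weight_map_r * convolved_rating_r + noise`:
#' a smooth positive baseline field (sum of broad Gaussian bumps), per-run
#' low-frequency drift (random cosines below `drift_max_freq_hz` with smooth
#' random spatial amplitude fields and run-specific phases), Gaussian
#' activation blobs confined to a gray-matter-like mask driven by
#' HRF-convolved ratings, and iid Gaussian noise. Independent random streams
#' are used per component, so e.g. changing `effect_amplitude` rescales the
#' signal term without altering mask, drift or noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_dataset`: `volumes` (4-D array),
#'   `gm_mask` (`mask_volume`), `true_weight_maps`, `raw_ratings`,
#'   `convolved_ratings` (per rating), `run_boundaries`, `hrf`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gd <- config$grid_dims
  n_run <- config$scans_per_run
  n_total <- n_run * config$n_runs
  run_boundaries <- split(seq_len(n_total),
                          rep(seq_len(config$n_runs), each = n_run))
  names(run_boundaries) <- NULL

  # stream 1: anatomy (baseline field + gray-matter mask)
  anat <- with_seed(sub_seed(config$seed, 1L), {
    baseline <- smooth_random_field(gd, n_bumps = 6, width_frac = 0.45,
                                    base = 100, amp = 40)
    gm_field <- smooth_random_field(gd, n_bumps = 8, width_frac = 0.3,
                                    base = 0, amp = 1)
    thr <- stats::quantile(gm_field, 0.7)
    list(baseline = baseline, mask = gm_field > thr)
  })
  if (!any(anat$mask)) stop("generated mask has no voxels")
  gm_mask <- mask_volume(anat$mask, config$voxel_size_mm)

  # stream 2: activation weight maps (Gaussian blobs inside the mask)
  wmaps <- with_seed(sub_seed(config$seed, 2L), {
    in_idx <- which(gm_mask$data != 0)
    lapply(seq_len(config$n_ratings), function(r) {
      centers <- arrayInd(sample(in_idx, config$n_active_blobs,
                                 replace = TRUE), gd)
      w <- array(0, gd)
      for (b in seq_len(config$n_active_blobs))
        w <- w + gaussian_blob(gd, centers[b, ], sd_vox = 1.5)
      w <- w / max(w)
      w * gm_mask$data
    })
  })

  # stream 3: ratings (raw, then HRF-convolved per run)
  hrf <- canonical_hrf(config$tr_seconds)
  H_run <- convolution_matrix(hrf, n_run)
  ratings <- with_seed(sub_seed(config$seed, 3L), {
    lapply(seq_len(config$n_ratings), function(r)
      generate_rating(config$rating_kinds[r], n_total,
                      seed = sample.int(2^30, 1),
                      tr_seconds = config$tr_seconds))
  })
  conv <- lapply(ratings, function(z) {
    out <- numeric(n_total)
    for (rb in run_boundaries) out[rb] <- drop(H_run %*% z[rb])
    out
  })

  n_vox <- prod(gd)
  flat <- matrix(rep(as.numeric(anat$baseline), n_total), nrow = n_vox)

  # stream 4: per-run low-frequency drift
  if (config$drift_amplitude > 0) {
    drift <- with_seed(sub_seed(config$seed, 4L), {
      d <- matrix(0, n_vox, n_total)
      tt <- (seq_len(n_run) - 1) * config$tr_seconds
      for (run in seq_len(config$n_runs)) {
        for (comp in 1:3) {
          f <- stats::runif(1, 0, config$drift_max_freq_hz)
          phase <- stats::runif(1, 0, 2 * pi)
          tc <- cos(2 * pi * f * tt + phase)
          field <- smooth_random_field(gd, n_bumps = 4, width_frac = 0.35,
                                       base = 0, amp = 1)
          field <- field - mean(field)
          d[, run_boundaries[[run]]] <- d[, run_boundaries[[run]]] +
            as.numeric(field) %o% tc
        }
      }
      d * config$drift_amplitude
    })
    flat <- flat + drift
  }

  # signal: linear in effect_amplitude by construction
  if (config$effect_amplitude > 0) {
    for (r in seq_len(config$n_ratings))
      flat <- flat + config$effect_amplitude *
        (as.numeric(wmaps[[r]]) %o% conv[[r]])
  }

  # stream 5: measurement noise
  if (config$noise_sd > 0) {
    noise <- with_seed(sub_seed(config$seed, 5L),
                       matrix(stats::rnorm(n_vox * n_total, sd = config$noise_sd),
                              n_vox, n_total))
    flat <- flat + noise
  }

  structure(list(volumes = array(flat, c(gd, n_total)),
                 gm_mask = gm_mask,
                 true_weight_maps = wmaps,
                 raw_ratings = ratings,
                 convolved_ratings = conv,
                 run_boundaries = run_boundaries,
                 hrf = hrf, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %s grid, %d runs x %d scans, %d rating(s) [%s]\n",
    paste(x$config$grid_dims, collapse = "x"), x$config$n_runs,
    x$config$scans_per_run, x$config$n_ratings,
    paste(x$config$rating_kinds, collapse = ", ")))
  invisible(x)
}

# Smooth positive random field: base + sum of broad Gaussian bumps at random
# centers. width_frac scales the bump sd relative to the grid.
smooth_random_field <- function(gd, n_bumps, width_frac, base, amp) {
  out <- array(base, gd)
  for (b in seq_len(n_bumps)) {
    ctr <- stats::runif(3) * (gd - 1) + 1
    out <- out + amp * gaussian_blob(gd, ctr, sd_vox = width_frac * mean(gd))
  }
  out
}

gaussian_blob <- function(gd, center, sd_vox) {
  dx <- (seq_len(gd[1]) - center[1])^2
  dy <- (seq_len(gd[2]) - center[2])^2
  dz <- (seq_len(gd[3]) - center[3])^2
  d2 <- outer(outer(dx, dy, "+"), dz, "+")
  exp(-d2 / (2 * sd_vox^2))
}
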