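#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a gamma-density peak minus a scaled
#' gamma-density undershoot, sampled at the repetition time and normalised to
#' unit peak. Defaults follow the standard convention: peak delay 6 s,
#' undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s
#' support.
#'
#' @param tr_seconds Sampling interval (TR) in seconds.
#' @param peak_delay,undershoot_delay Delays of response and undershoot (s).
#' @param peak_disp,undershoot_disp Dispersions (s); must be positive.
#' @param ratio Peak-to-undershoot amplitude ratio (undershoot is divided by
#'   this).
#' @param duration Support length in seconds.
#' @return An object of class `hrf_kernel` with `samples` (peak 1) and the
#'   parameter set.
#' @export
canonical_hrf <- function(tr_seconds, peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1, ratio = 6,
                          duration = 32) {
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (peak_disp <= 0 || undershoot_disp <= 0) stop("dispersions must be positive")
  if (duration < peak_delay) stop("duration must cover the peak delay")
  tt <- seq(0, duration, by = tr_seconds)
  samples <- hrf_shape(tt, peak_delay, undershoot_delay, peak_disp,
                       undershoot_disp, ratio)
  samples <- samples / max(samples)
  structure(list(samples = samples, tr_seconds = tr_seconds,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_disp = peak_disp,
                               undershoot_disp = undershoot_disp,
                               ratio = ratio, duration = duration)),
            class = "hrf_kernel")
}

# Raw (un-normalised) double-gamma shape evaluated at times tt (seconds).
hrf_shape <- function(tt, peak_delay, undershoot_delay, peak_disp,
                      undershoot_disp, ratio) {
  stats::dgamma(tt, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(tt, shape = undershoot_delay / undershoot_disp,
                  scale = undershoot_disp) / ratio
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("hrf_kernel: %d samples at TR %.3g s (peak delay %g s)\n",
              length(x$samples), x$tr_seconds, x$params$peak_delay))
  invisible(x)
}

#' Toeplitz convolution matrix of an HRF
#'
#' The `N x N` lower-triangular Toeplitz matrix `H` with
#' `H[i, j] = hrf[i - j]` for `i >= j`, so that `t = H z_raw` is the causal
#' discrete convolution of a raw rating with the HRF, truncated to `N` scans.
#'
#' @param hrf An `hrf_kernel` (or numeric sample vector).
#' @param N Number of scans.
#' @return `N x N` numeric matrix.
#' @export
convolution_matrix <- function(hrf, N) {
  h <- if (inherits(hrf, "hrf_kernel")) hrf$samples else as.numeric(hrf)
  h <- c(h, numeric(max(0, N - length(h))))[seq_len(N)]
  H <- matrix(0, N, N)
  for (j in seq_len(N)) H[j:N, j] <- h[seq_len(N - j + 1)]
  H
}

#' Box-constrained deconvolution of a predicted rating
#'
#' Recovers the raw rating underlying a model prediction by solving the
#' quadratic program
#' `min_z ||H z - t*||^2  subject to  0 <= z <= 1`,
#' exploiting the prior knowledge that raw ratings live in the unit interval.
#' The convex bound-constrained problem is solved to KKT tolerance by a
#' quasi-Newton method with projected box constraints and analytic gradient.
#'
#' @param t_star Predicted (convolved-scale) rating vector.
#' @param H Convolution matrix from [convolution_matrix()].
#' @param tol Convergence control (objective reduction factor for the solver).
#' @return Numeric vector `z_raw` in \[0, 1\].
#' @export
deconvolve_constrained <- function(t_star, H, tol = 1e-12) {
  N <- length(t_star)
  if (!is.matrix(H) || nrow(H) != N || ncol(H) != N)
    stop("H must be an N x N convolution matrix matching t_star")
  HtH <- crossprod(H)
  Htt <- drop(crossprod(H, t_star))
  fn <- function(z) sum((H %*% z - t_star)^2)
  gr <- function(z) 2 * (HtH %*% z - Htt)
  # warm start: unconstrained least squares clipped to the box
  z0 <- tryCatch(pmin(1, pmax(0, solve(HtH + diag(1e-10, N), Htt))),
                 error = function(e) rep(0.5, N))
  fit <- stats::optim(z0, fn, gr, method = "L-BFGS-B",
                      lower = rep(0, N), upper = rep(1, N),
                      control = list(maxit = 2000, factr = tol / .Machine$double.eps))
  if (fit$convergence != 0)
    stop(sprintf("constrained deconvolution did not converge (code %d: %s)",
                 fit$convergence, fit$message))
  pmin(1, pmax(0, fit$par))
}

#' Re-convolve a deconvolved rating and smooth it temporally
#'
#' The furnished prediction: `t = H z_raw`, followed by 1-D Gaussian
#' smoothing with a FWHM given in scans (TR units; default 3). The smoothing
#' kernel is truncated and renormalised at the series edges.
#'
#' @param z_raw Raw rating vector in \[0, 1\].
#' @param H Convolution matrix.
#' @param fwhm_tr Temporal FWHM in scans; 0 disables smoothing.
#' @return Final prediction vector.
#' @export
reconvolve_smooth <- function(z_raw, H, fwhm_tr = 3) {
  if (fwhm_tr < 0) stop("fwhm_tr must be >= 0")
  t_new <- drop(H %*% z_raw)
  smooth_vector_gaussian(t_new, fwhm_tr)
}

#' Shift a rating in time (and undo the shift)
#'
#' `temporal_shift(v, k)` delays the series by `k` scans (`k < 0` advances
#' it), padding with edge replication so no spurious onsets are created;
#' `inverse_shift(v, k)` applies the opposite shift. Round-tripping restores
#' the series except within `|k|` samples of the edges. Used to train against
#' targets shifted earlier/later when a region's hemodynamic delay differs
#' from the canonical HRF.
#'
#' @param v Numeric vector.
#' @param k Integer shift in scans; `|k| < length(v) / 4`.
#' @return Shifted vector of the same length.
#' @export
temporal_shift <- function(v, k) {
  n <- length(v)
  k <- as.integer(k)
  if (abs(k) >= n / 4) stop("|k| must be less than N/4")
  if (k == 0) return(v)
  idx <- pmin(n, pmax(1, seq_len(n) - k))
  v[idx]
}

#' @rdname temporal_shift
#' @export
inverse_shift <- function(v, k) temporal_shift(v, -k)

#' Average spike template from event-containing ratings
#'
#' Detects contiguous supra-threshold segments (spikes) in each rating,
#' aligns them at onset, averages across all events, and normalises the
#' result to unit peak. Segments are padded to the longest event with their
#' trailing value.
#'
#' @param ratings List of numeric rating vectors (or a single vector).
#' @param threshold Values strictly above this belong to a spike.
#' @return Numeric template vector, peak 1.
#' @export
build_spike_template <- function(ratings, threshold = 0) {
  if (is.numeric(ratings)) ratings <- list(ratings)
  segs <- list()
  for (r in ratings) {
    on <- r > threshold
    if (!any(on)) next
    d <- diff(c(FALSE, on, FALSE))
    starts <- which(d == 1)
    ends <- which(d == -1) - 1L
    for (i in seq_along(starts)) segs[[length(segs) + 1L]] <- r[starts[i]:ends[i]]
  }
  if (length(segs) == 0) stop("no spikes found above threshold")
  len <- max(lengths(segs))
  m <- vapply(segs, function(s) c(s, rep(s[length(s)], len - length(s))),
              numeric(len))
  tmpl <- rowMeans(matrix(m, nrow = len))
  tmpl / max(tmpl)
}

#' Match-filter detection and template insertion
#'
#' Cross-correlates a prediction with a known event template, picks the
#' `k_events` best-fitting onsets by greedy non-maximum suppression
#' (exclusion radius = template length, ties to the earliest lag), and
#' returns a clean reconstruction: a zero baseline with the template inserted
#' at each detected onset.
#'
#' @param pred Prediction vector.
#' @param template Event template (shorter than `pred`).
#' @param k_events Number of events to place (default 7).
#' @return Reconstructed rating vector with attribute `"lags"` (1-based
#'   onsets, sorted).
#' @export
match_filter_insert <- function(pred, template, k_events = 7) {
  n <- length(pred)
  m <- length(template)
  if (m >= n) stop("template must be shorter than the prediction")
  if (k_events < 1) stop("k_events must be >= 1")
  n_lags <- n - m + 1L
  score <- vapply(seq_len(n_lags),
                  function(s) sum(pred[s:(s + m - 1L)] * template),
                  numeric(1))
  chosen <- integer(0)
  avail <- rep(TRUE, n_lags)
  for (i in seq_len(k_events)) {
    if (!any(avail)) stop(sprintf(
      "only %d admissible event lags for %d requested events", i - 1L, k_events))
    cand <- which(avail)
    best <- cand[order(-score[cand], cand)][1]   # ties -> earliest lag
    chosen <- c(chosen, best)
    avail[max(1L, best - m + 1L):min(n_lags, best + m - 1L)] <- FALSE
  }
  out <- numeric(n)
  for (s in chosen) {
    seg <- s:(s + m - 1L)
    out[seg] <- pmax(out[seg], template)
  }
  attr(out, "lags") <- sort(chosen)
  out
}
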