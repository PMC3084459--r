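#' Pipeline configuration
#'
#' Schema-validated settings for the full decoding pipeline. Unknown keys are
#' rejected.
#'
#' @param preprocessing List: `fwhm_mm` (spatial smoothing FWHM, mm; 0
#'   disables), `dct_bases` (number of DCT drift bases `L` incl. the
#'   constant; 0 disables detrending), `per_run` (block-diagonal detrending
#'   over runs).
#' @param kernel List: `kind` (`"linear"`, `"rbf"`, `"polynomial"`), `gamma`
#'   (RBF width; `NULL` = median heuristic), `theta`, `degree` (polynomial).
#' @param model List: `type` (`"krr"`, `"rvr"`, `"evidence"`); for KRR either
#'   a scalar `lambda` or a `lambda_grid` selected by cross-validated mean
#'   Fisher z; `include_constant` for the evidence optimiser.
#' @param postprocessing List: `deconvolve` (constrained deconvolution +
#'   re-convolution), `fwhm_tr` (temporal smoothing FWHM in scans),
#'   `shift_k` (train-target temporal shift in scans; predictions are
#'   inversely shifted), `match_filter` (`NULL` or a list with `k_events`,
#'   `threshold`).
#' @param seed Seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocessing = list(), kernel = list(),
                            model = list(), postprocessing = list(),
                            seed = 1) {
  pp <- merge_defaults(preprocessing,
                       list(fwhm_mm = 0, dct_bases = 8, per_run = TRUE),
                       "preprocessing")
  kk <- merge_defaults(kernel,
                       list(kind = "linear", gamma = NULL, theta = 1,
                            degree = 2), "kernel")
  mm <- merge_defaults(model,
                       list(type = "krr", lambda = 100, lambda_grid = NULL,
                            include_constant = FALSE, tol = 1e-6,
                            max_iter = 1000), "model")
  po <- merge_defaults(postprocessing,
                       list(deconvolve = FALSE, fwhm_tr = 3, shift_k = 0,
                            match_filter = NULL), "postprocessing")
  if (!kk$kind %in% c("linear", "rbf", "polynomial"))
    stop("kernel kind must be linear, rbf or polynomial")
  if (!mm$type %in% c("krr", "rvr", "evidence"))
    stop("model type must be krr, rvr or evidence")
  structure(list(preprocessing = pp, kernel = kk, model = mm,
                 postprocessing = po, seed = seed),
            class = "pipeline_config")
}

merge_defaults <- function(given, defaults, section) {
  if (is.null(given)) given <- list()
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", section,
                 paste(unknown, collapse = ", ")))
  defaults[names(given)] <- given
  defaults
}

#' Session-wise cross-validation of the decoding pipeline
#'
#' For each held-out run: fit on the remaining runs, predict the held-out
#' scans, post-process per the configuration, and score the prediction
#' against the held-out HRF-convolved rating. Kernel detrending uses one
#' residual-forming matrix built over the concatenated train + test scan set
#' (block-diagonal per run), applied to the joint linear kernel before
#' slicing train/test blocks. With a KRR `lambda_grid`, every fold is
#' evaluated at each grid value and the penalty with the best mean Fisher z
#' is selected (the per-grid aggregate is attached as attribute `"grid"`).
#'
#' @param dataset A `synthetic_dataset`, or a list with fields `volumes`,
#'   `gm_mask`, `convolved_ratings` (named list), `run_boundaries`, `config`
#'   (with `tr_seconds`, `voxel_size_mm`) and optionally `raw_ratings`.
#' @param config A [pipeline_config()].
#' @param subject Label for the score table.
#' @return A [score_table()] with one row per (rating, held-out run).
#' @export
cross_validate <- function(dataset, config = pipeline_config(),
                           subject = "sim") {
  stopifnot(inherits(config, "pipeline_config"))
  rb <- dataset$run_boundaries
  if (length(rb) < 2) stop("cross-validation needs at least 2 runs")
  prep <- prepare_kernel(dataset, config)
  ratings <- dataset$convolved_ratings
  if (is.null(names(ratings)))
    names(ratings) <- paste0("rating", seq_along(ratings))

  if (config$model$type == "krr" && !is.null(config$model$lambda_grid)) {
    grid <- config$model$lambda_grid
    tables <- lapply(grid, function(lam) {
      cfg <- config
      cfg$model$lambda <- lam
      cfg$model$lambda_grid <- NULL
      cv_all_folds(dataset, cfg, prep, ratings, subject)
    })
    agg <- vapply(tables, aggregate_score, numeric(1))
    best <- which.max(agg)
    out <- tables[[best]]
    attr(out, "grid") <- data.frame(lambda = grid, mean_fisher_z = agg)
    attr(out, "lambda") <- grid[best]
    return(out)
  }
  cv_all_folds(dataset, config, prep, ratings, subject)
}

# Shared preprocessing: smooth, mask, joint linear kernel, joint detrending.
prepare_kernel <- function(dataset, config) {
  pp <- config$preprocessing
  vols <- dataset$volumes
  if (any(pp$fwhm_mm > 0))
    vols <- smooth_volumes(vols, pp$fwhm_mm, dataset$config$voxel_size_mm)
  ts <- apply_mask(vols, dataset$gm_mask, dataset$run_boundaries)
  K <- linear_kernel(ts)
  drift <- NULL
  if (pp$dct_bases > 0) {
    drift <- build_dct_basis(ts$N, pp$dct_bases,
                             if (isTRUE(pp$per_run)) ts$run_boundaries else NULL)
    K <- detrend_kernel(K, drift)
  }
  list(ts = ts, K = K, drift = drift)
}

cv_all_folds <- function(dataset, config, prep, ratings, subject) {
  rb <- dataset$run_boundaries
  n_run_scans <- lengths(rb)
  H_runs <- lapply(n_run_scans, function(n)
    convolution_matrix(canonical_hrf(dataset$config$tr_seconds), n))
  rows <- list()
  for (rname in names(ratings)) {
    target <- ratings[[rname]]
    for (fold in seq_along(rb)) {
      test_idx <- rb[[fold]]
      train_idx <- sort(unlist(rb[-fold]))
      pred <- decode_fold(prep, config, target, train_idx, test_idx)
      pred <- postprocess_prediction(pred, config$postprocessing,
                                     H_runs[[fold]], target[train_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, rating = rname, session = fold,
        pearson = pearson_r(pred, target[test_idx]))
    }
  }
  df <- do.call(rbind, rows)
  score_table(df$subject, df$rating, df$session, df$pearson)
}

# Fit on train_idx, predict test_idx, honouring kernel kind, model type and
# the train-target temporal shift.
decode_fold <- function(prep, config, target, train_idx, test_idx) {
  kk <- config$kernel
  V <- prep$K$values
  K_tr <- V[train_idx, train_idx, drop = FALSE]
  K_te <- V[test_idx, train_idx, drop = FALSE]
  if (kk$kind == "rbf") {
    Ktr_km <- kernel_matrix(K_tr, "linear", check = FALSE)
    gamma <- kk$gamma %||% rbf_gamma_heuristic(Ktr_km)
    K_tr <- rbf_from_linear(Ktr_km, gamma)$values
    K_te <- rbf_from_linear(kernel_matrix(K_te, "linear", check = FALSE),
                            gamma, diag_rows = diag(V)[test_idx],
                            diag_cols = diag(V)[train_idx])$values
  } else if (kk$kind == "polynomial") {
    K_tr <- (kk$theta + K_tr)^kk$degree
    K_te <- (kk$theta + K_te)^kk$degree
  }
  t_train <- target[train_idx]
  k_shift <- config$postprocessing$shift_k
  if (k_shift != 0) t_train <- temporal_shift(t_train, k_shift)
  mm <- config$model
  model <- switch(mm$type,
    krr = fit_krr(K_tr, t_train, mm$lambda),
    rvr = fit_rvr(K_tr, t_train, tol = mm$tol, max_iter = mm$max_iter),
    evidence = {
      hp <- optimize_evidence(K_tr, t_train,
                              include_constant = isTRUE(mm$include_constant),
                              seed = config$seed)
      fit_krr(K_tr, t_train, hp$lambda)
    })
  pred <- predict_kernel_model(model, K_te)
  if (k_shift != 0) pred <- inverse_shift(pred, k_shift)
  pred
}

# HRF-aware post-processing of a held-out prediction.
postprocess_prediction <- function(pred, po, H_test, train_target) {
  if (isTRUE(po$deconvolve)) {
    z <- deconvolve_constrained(pred, H_test)
    pred <- reconvolve_smooth(z, H_test, po$fwhm_tr)
  }
  if (!is.null(po$match_filter)) {
    mf <- po$match_filter
    tmpl <- build_spike_template(train_target,
                                 threshold = mf$threshold %||% 0)
    pred <- match_filter_insert(pred, tmpl, k_events = mf$k_events %||% 7)
  }
  pred
}
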