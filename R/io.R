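#' Write a synthetic dataset to a directory
#'
#' Persists the standard exchange layout: `volumes.nii.gz` and
#' `mask.nii.gz` (NIfTI-1), `ratings.csv` and `convolved_ratings.csv`
#' (one column per rating plus a `run` index column, one row per scan), and
#' `config.yaml`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pix <- dataset$config$voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(dataset$volumes,
                                     pixdim = c(pix, dataset$config$tr_seconds)),
                     file.path(dir, "volumes.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(dataset$gm_mask$data + 0, pixdim = pix),
                     file.path(dir, "mask.nii.gz"))
  write_ratings_csv(dataset$raw_ratings, dataset$run_boundaries,
                    file.path(dir, "ratings.csv"))
  write_ratings_csv(dataset$convolved_ratings, dataset$run_boundaries,
                    file.path(dir, "convolved_ratings.csv"))
  cfg <- unclass(dataset$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `volumes.nii.gz`, `mask.nii.gz`,
#'   `convolved_ratings.csv` and `config.yaml`.
#' @return A list with the `synthetic_dataset` fields needed by
#'   [cross_validate()] (ground-truth weight maps are not persisted).
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  vols <- array(as.numeric(RNifti::readNifti(file.path(dir, "volumes.nii.gz"))),
                dim = dim(RNifti::readNifti(file.path(dir, "volumes.nii.gz"))))
  mask <- mask_volume(array(as.numeric(RNifti::readNifti(file.path(dir, "mask.nii.gz"))),
                            dim = cfg$grid_dims),
                      cfg$voxel_size_mm)
  conv <- read_ratings_csv(file.path(dir, "convolved_ratings.csv"))
  raw_path <- file.path(dir, "ratings.csv")
  raw <- if (file.exists(raw_path)) read_ratings_csv(raw_path) else NULL
  structure(list(volumes = vols, gm_mask = mask,
                 raw_ratings = raw$ratings,
                 convolved_ratings = conv$ratings,
                 run_boundaries = conv$run_boundaries,
                 config = cfg),
            class = "synthetic_dataset")
}

#' Write rating time courses as CSV
#'
#' One row per scan: a `run` index column followed by one column per rating.
#'
#' @param ratings Named (or unnamed) list of numeric vectors.
#' @param run_boundaries List of per-run scan index vectors.
#' @param path Output CSV path.
#' @export
write_ratings_csv <- function(ratings, run_boundaries, path) {
  if (is.null(names(ratings)) || any(names(ratings) == ""))
    names(ratings) <- paste0("rating", seq_along(ratings))
  n <- length(ratings[[1]])
  run <- integer(n)
  for (i in seq_along(run_boundaries)) run[run_boundaries[[i]]] <- i
  df <- data.frame(run = run, ratings, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read rating time courses from CSV
#'
#' @param path CSV with a `run` column and one column per rating.
#' @return List with `ratings` (named list of vectors) and `run_boundaries`.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run" %in% names(df)) stop("ratings CSV must contain a 'run' column")
  runs <- sort(unique(df$run))
  rb <- lapply(runs, function(r) which(df$run == r))
  ratings <- as.list(df[setdiff(names(df), "run")])
  list(ratings = ratings, run_boundaries = rb)
}

#' Read a pipeline configuration from YAML
#'
#' Parses and schema-validates a YAML file into a [pipeline_config()];
#' unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("preprocessing", "kernel", "model", "postprocessing", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown pipeline config key(s): %s",
                 paste(unknown, collapse = ", ")))
  pipeline_config(preprocessing = y$preprocessing, kernel = y$kernel,
                  model = y$model, postprocessing = y$postprocessing,
                  seed = y$seed %||% 1)
}

#' Write a 3-D map (e.g. a weight map) as NIfTI-1
#'
#' @param map 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions recorded in the header.
#' @export
write_map_nifti <- function(map, path, voxel_size_mm = c(3, 3, 3)) {
  RNifti::writeNifti(RNifti::asNifti(map, pixdim = voxel_size_mm), path)
  invisible(path)
}
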