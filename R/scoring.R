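#' Pearson correlation between a prediction and its target
#'
#' Standard sample correlation. Constant inputs make the correlation
#' undefined and raise an error.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input")
  stats::cor(a, b)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r) = 0.5 log((1 + r) / (1 - r))`, the variance-stabilising map
#' used to aggregate correlations: it squashes unremarkable correlations
#' together and stretches remarkable ones, so a gain from 0.8 to 0.9 counts
#' roughly three times a gain from 0.2 to 0.3. Correlations at or beyond
#' `|r| = 1 - 1e-7` are clipped with a warning (near-perfect reconstructions
#' would otherwise map to infinity).
#'
#' @param r Correlation value(s).
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  clip <- 1 - 1e-7
  if (any(abs(r) >= clip)) {
    warning("|r| >= 1 - 1e-7; clipping before Fisher transform")
    r <- pmin(clip, pmax(-clip, r))
  }
  atanh(r)
}

#' Assemble a score table
#'
#' One row per (subject, rating, session) cell with the Pearson correlation
#' and its Fisher z; the competition-style aggregate is the arithmetic mean
#' of the z column.
#'
#' @param subject,rating,session Vectors identifying each cell.
#' @param pearson Correlation per cell.
#' @return A `data.frame` of class `score_table` with columns `subject`,
#'   `rating`, `session`, `pearson_r`, `fisher_z`.
#' @export
score_table <- function(subject, rating, session, pearson) {
  df <- data.frame(subject = subject, rating = rating, session = session,
                   pearson_r = pearson, fisher_z = fisher_z(pearson),
                   stringsAsFactors = FALSE)
  class(df) <- c("score_table", "data.frame")
  df
}

#' Aggregate competition score
#'
#' Arithmetic mean of the Fisher z scores over all included cells.
#'
#' @param table A `score_table` (or data frame with a `fisher_z` column).
#' @return Mean Fisher z.
#' @export
aggregate_score <- function(table) {
  if (nrow(table) == 0) stop("empty score table")
  mean(table$fisher_z)
}

#' @export
print.score_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("aggregate (mean Fisher z): %.4f\n", aggregate_score(x)))
  invisible(x)
}
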