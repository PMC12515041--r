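#' Robust centered log-ratio transform
#'
#' Each non-zero entry becomes `ln(value / g)` where `g` is the geometric
#' mean of that sample's non-zero entries; zero cells are returned as `NA`
#' (treated as missing, the rCLR convention, rather than pseudocounted).
#' Each row of the result has mean zero over its non-missing entries.
#'
#' @param table non-negative feature table; every sample needs at least one
#'   non-zero feature.
#' @return samples x features matrix with `NA` where the input was zero.
#' @export
rclr <- function(table) {
  validate_feature_table(table)
  if (any(rowSums(table > 0) == 0)) stop("rclr: sample with all-zero counts")
  lg <- log(table)
  lg[table == 0] <- NA
  sweep(lg, 1, rowMeans(lg, na.rm = TRUE))
}

#' Repeated-observations correlation between two series
#'
#' The within-subject correlation of Bland and Altman for designs where
#' each subject contributes several observations: both series are centred
#' on their subject means and the centred sums of products are pooled
#' across subjects,
#' \deqn{r = \sum_{ij}(x_{ij}-\bar x_i)(y_{ij}-\bar y_i) /
#'   \sqrt{\sum_{ij}(x_{ij}-\bar x_i)^2 \sum_{ij}(y_{ij}-\bar y_i)^2}.}
#' Observations where either value is missing are dropped (pairwise
#' complete) before the subject means are computed.  With a single subject
#' this reduces to the ordinary Pearson correlation of its observations.
#'
#' @param x,y numeric vectors, aligned; may contain `NA` (e.g. rCLR zeros).
#' @param subject subject labels aligned with `x` and `y`.
#' @return the correlation, or `NA` when fewer than 3 complete observations
#'   remain or a series has zero within-subject variance.
#' @export
rm_correlation <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject))
    stop("x, y and subject must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; s <- as.character(subject)[ok]
  if (length(x) < 3) return(NA_real_)
  xc <- x - ave(x, s)
  yc <- y - ave(y, s)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Repeated-observations correlation matrix between all features
#'
#' Applies [rm_correlation()] to every pair of feature columns of an rCLR
#' matrix, pairwise-complete over the cells that are non-missing in both
#' features.  The baseline and end-of-study samples of a mouse are that
#' subject's repeated observations.  Pairs whose correlation is undefined
#' (zero within-subject variance or too few shared observations) are set
#' to 0 — a neutral distance of 1 downstream — and their count reported in
#' a message.
#'
#' @param m rCLR matrix (samples x features, `NA` = missing).
#' @param meta sample metadata with `sample_id` and `subject_id`; every row
#'   of `m` must have a metadata row.
#' @return symmetric features x features correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(m, meta) {
  idx <- match(rownames(m), meta$sample_id)
  if (anyNA(idx)) stop("every sample in the matrix needs a metadata row")
  subj <- as.integer(factor(meta$subject_id[idx])) - 1L
  r <- .rm_corr_matrix_cpp(m, subj, max(subj) + 1L)
  dimnames(r) <- list(colnames(m), colnames(m))
  n_undef <- sum(is.na(r[upper.tri(r)]))
  if (n_undef > 0) {
    message(sprintf("correlation_matrix: %d undefined pair(s) set to 0", n_undef))
    r[is.na(r)] <- 0
  }
  r
}

#' Correlation to distance
#'
#' `d = 1 - r`: perfectly co-abundant features are at distance 0,
#' perfectly anti-correlated ones at distance 2.
#'
#' @param r symmetric correlation matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
corr_to_distance <- function(r) {
  if (!isSymmetric(unname(r))) stop("correlation matrix must be symmetric")
  d <- 1 - r
  diag(d) <- 0
  d
}

#' @rdname correlation_matrix
#' @param path output TSV path (square matrix with feature ids).
#' @export
write_correlation_matrix <- function(r, path) {
  df <- data.frame(`feature-id` = rownames(r), r, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
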