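#' Alpha diversity per sample
#'
#' Observed features (non-zero count) and Shannon's index
#' \eqn{H = -\sum p_i \log_b p_i} over non-zero proportions; base 2 by
#' default (bits), natural log available.
#'
#' @param table count feature table; every sample must have positive total.
#' @param base logarithm base for Shannon (2 or `exp(1)`).
#' @return data.frame with sample_id, observed, shannon.
#' @export
alpha_diversity <- function(table, base = 2) {
  validate_feature_table(table)
  if (any(rowSums(table) == 0)) stop("zero-sum sample in alpha_diversity")
  obs <- rowSums(table > 0)
  sh <- apply(table, 1, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p, base = base))
  })
  data.frame(sample_id = rownames(table), observed = as.integer(obs),
             shannon = sh, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)} between sample
#' abundance vectors.
#'
#' @param table non-negative feature table with positive sample sums.
#' @return symmetric samples x samples distance matrix.
#' @export
bray_curtis <- function(table) {
  validate_feature_table(table)
  if (any(rowSums(table) == 0)) stop("zero-sum sample in bray_curtis")
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Principal coordinate analysis
#'
#' Eigendecomposition of the Gower double-centred \eqn{-d^2/2} matrix.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues; negative eigenvalues are reported but excluded
#' from the coordinates (no Cailliez correction).
#'
#' @param d symmetric distance matrix.
#' @return an `ordination`: list with `coordinates` (samples x axes,
#'   columns PC1...), `eigenvalues` (all, decreasing, negatives included)
#'   and `proportion_explained` (relative to the positive-eigenvalue sum).
#' @export
pcoa <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PC", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 proportion_explained = e$values / sum(e$values[e$values > 0])),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- x$proportion_explained[seq_len(min(3, ncol(x$coordinates)))]
  cat("  proportion explained:", paste(sprintf("%.1f%%", 100 * pe),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Write an ordination in a QIIME2-style plain-text layout
#'
#' @param ord an `ordination`.
#' @param path output path.
#' @export
write_ordination <- function(ord, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ev <- ord$eigenvalues
  writeLines(sprintf("Eigvals\t%d", length(ev)), con)
  writeLines(paste(format(ev, digits = 12), collapse = "\t"), con)
  writeLines("", con)
  writeLines(sprintf("Proportion explained\t%d", length(ev)), con)
  writeLines(paste(format(ord$proportion_explained, digits = 12),
                   collapse = "\t"), con)
  writeLines("", con)
  co <- ord$coordinates
  writeLines(sprintf("Site\t%d\t%d", nrow(co), ncol(co)), con)
  for (i in seq_len(nrow(co)))
    writeLines(paste(c(rownames(co)[i], format(co[i, ], digits = 12)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Runs [permanova()] for every pair of groups and adjusts the p-values
#' across pairs with the BH step-up procedure.
#'
#' @param d samples x samples distance matrix.
#' @param groups group labels per sample (>= 2 groups).
#' @param n_perm permutations per pairwise test (default 9999).
#' @param seed optional seed.
#' @return data.frame with group1, group2, F, p, q.
#' @export
permanova_pairwise <- function(d, groups, n_perm = 9999, seed = NULL) {
  D <- as.matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  pairs <- combn(levels(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    idx <- groups %in% pr
    pv <- permanova(D[idx, idx, drop = FALSE], droplevels(groups[idx]),
                    n_perm = n_perm)
    data.frame(group1 = pr[1], group2 = pr[2], F = pv$F, p = pv$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Procrustes concordance of two ordinations
#'
#' Superimposes ordination `b` onto `a` by centering, scaling to unit sum
#' of squares and optimal rotation (symmetric Procrustes); the residual
#' sum of squares \eqn{m_{12}^2 \in [0, 1]} is 0 iff the configurations
#' are identical up to translation, rotation and scaling.  Significance is
#' assessed by PROTEST: permuting the sample rows of `b`,
#' `p = (1 + #[m12'^2 <= m12^2]) / (1 + n_perm)`.  Both ordinations are
#' truncated to their shared count of positive axes before comparison.
#'
#' @param a,b `ordination` objects over the same samples.
#' @param n_perm PROTEST permutations (default 999).
#' @param seed optional seed.
#' @param k_axes number of axes to compare; default the minimum positive
#'   axis count of the two ordinations (use 2 for a plot-level
#'   comparison).
#' @return list with `m12_squared`, `protest_p`, `n_perm`, `k_axes`.
#' @export
procrustes_compare <- function(a, b, n_perm = 999, seed = NULL,
                               k_axes = NULL) {
  X <- a$coordinates
  Y <- b$coordinates
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !setequal(rownames(X), rownames(Y)))
    stop("ordinations must cover the same samples")
  Y <- Y[rownames(X), , drop = FALSE]
  k <- min(ncol(X), ncol(Y))
  if (!is.null(k_axes)) k <- min(k, k_axes)
  X <- X[, seq_len(k), drop = FALSE]
  Y <- Y[, seq_len(k), drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  pr <- vegan::protest(X, Y, permutations = n_perm, symmetric = TRUE)
  list(m12_squared = unname(pr$ss), protest_p = unname(pr$signif),
       n_perm = n_perm, k_axes = k)
}

#' Information-loss score
#'
#' Ratio of the genus-level to the CAG-level Procrustes residual
#' (\eqn{m_{12}^2}) against the same full-resolution ASV ordination; a
#' score above 1 means the genus summary lost more community structure
#' than the guild summary.  When the CAG-level residual is 0 the ratio is
#' undefined and `NA` is returned (with attribute `undefined = TRUE`).
#'
#' @param m2_genus genus-level \eqn{m_{12}^2} (>= 0).
#' @param m2_cag CAG-level \eqn{m_{12}^2} (>= 0).
#' @return the ratio, or `NA` flagged undefined when `m2_cag` is 0.
#' @export
information_loss <- function(m2_genus, m2_cag) {
  if (m2_genus < 0 || m2_cag < 0) stop("m12^2 values cannot be negative")
  if (m2_cag == 0) {
    message("information_loss: reference m12^2 is 0; score undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  m2_genus / m2_cag
}
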