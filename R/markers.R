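#' Boruta-style shadow-feature selection
#'
#' All-relevant feature selection around a random forest.  Each iteration
#' appends a "shadow" copy of every still-undecided feature (its values
#' permuted across samples, destroying any association with the labels),
#' fits a forest on real + shadow features, and records each feature's
#' importance Z-score (mean decrease in accuracy divided by its standard
#' deviation over trees).  A feature scores a hit when its Z exceeds the
#' best shadow Z of that iteration.  Hit counts are tested against the
#' coin-flip null with a two-sided binomial test (p = 0.5), Bonferroni
#' corrected across the starting features: significantly more hits than
#' chance confirms a feature, significantly fewer rejects it (and removes
#' it from later iterations).  Features undecided after `n_iter`
#' iterations are reported tentative.
#'
#' @param x samples x features numeric matrix.
#' @param y two-class labels (factor or coercible), >= 2 samples per
#'   class.
#' @param n_iter maximum iterations (default 100, >= 10).
#' @param n_trees trees per forest (default 500).
#' @param alpha significance level of the binomial decision (default
#'   0.01).
#' @param seed optional seed.
#' @return a `boruta_result`: list with `status` (named vector in
#'   confirmed/rejected/tentative), `hits`, `n_iter` (iterations
#'   completed), `z_history` (features x iterations, `NA` once a feature
#'   is dropped) and `shadow` (per-iteration min/mean/max shadow Z).
#' @export
boruta <- function(x, y, n_iter = 100, n_trees = 500, alpha = 0.01,
                   seed = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) stop("boruta needs exactly two classes")
  if (min(table(y)) < 2) stop("each class needs >= 2 samples")
  if (n_iter < 10) stop("n_iter must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(p))
  colnames(x) <- feats
  status <- setNames(rep("tentative", p), feats)
  hits <- setNames(integer(p), feats)
  z_hist <- matrix(NA_real_, p, n_iter, dimnames = list(feats, NULL))
  shadow <- matrix(NA_real_, n_iter, 3,
                   dimnames = list(NULL, c("min", "mean", "max")))
  iter <- 0L
  for (it in seq_len(n_iter)) {
    active <- names(status)[status == "tentative"]
    if (length(active) == 0) break
    iter <- it
    xa <- x[, active, drop = FALSE]
    sh <- apply(xa, 2, sample)
    colnames(sh) <- paste0("shadow_", active)
    rf <- randomForest::randomForest(cbind(xa, sh), y, ntree = n_trees,
                                     importance = TRUE)
    z <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    z[!is.finite(z)] <- 0
    zs <- z[colnames(sh)]
    za <- z[active]
    z_hist[active, it] <- za
    shadow[it, ] <- c(min(zs), mean(zs), max(zs))
    hits[active] <- hits[active] + (za > max(zs))
    if (it >= 5) {
      for (f in active) {
        pv <- binom.test(hits[[f]], it, p = 0.5)$p.value
        if (pv * p < alpha)
          status[f] <- if (hits[[f]] > it / 2) "confirmed" else "rejected"
      }
    }
  }
  structure(list(status = status, hits = hits, n_iter = iter,
                 z_history = z_hist[, seq_len(iter), drop = FALSE],
                 shadow = as.data.frame(shadow[seq_len(iter), , drop = FALSE])),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$status, c("confirmed", "tentative", "rejected")))
  cat(sprintf("boruta_result after %d iteration(s): %d confirmed, %d tentative, %d rejected\n",
              x$n_iter, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' @rdname boruta
#' @param b a `boruta_result`.
#' @param path output TSV (feature, status, median Z).
#' @export
write_boruta <- function(b, path) {
  med <- apply(b$z_history, 1, median, na.rm = TRUE)
  write.table(data.frame(feature = names(b$status), status = unname(b$status),
                         median_z = unname(med)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROC curve and trapezoidal AUC from scores
#'
#' @param scores numeric decision scores, larger = more positive-class.
#' @param labels two-class labels; the second factor level is the
#'   positive class.
#' @return list with `roc` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("roc_auc needs two classes")
  pos <- labels == levels(labels)[2]
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[last])),
       auc = auc)
}

#' Cross-validated random-forest classification AUC
#'
#' Repeated stratified cross-validation of a random-forest classifier on
#' the selected features; out-of-fold class probabilities are averaged
#' over repeats per sample and summarised as a trapezoidal ROC/AUC.
#'
#' @param x samples x selected-features matrix (non-empty).
#' @param y two-class labels.
#' @param cv_folds folds (default 5; reduced to the smaller class size if
#'   needed so every training fold holds both classes).
#' @param cv_repeats repeats (default 5).
#' @param n_trees trees per forest (default 500).
#' @param seed optional seed.
#' @return list with `roc`, `auc` and the per-sample out-of-fold `scores`.
#' @export
classifier_auc <- function(x, y, cv_folds = 5, cv_repeats = 5,
                           n_trees = 500, seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("selected feature set is empty")
  y <- factor(y)
  if (nlevels(y) != 2) stop("classifier_auc needs two classes")
  if (min(table(y)) < 2) stop("each class needs >= 2 samples")
  cv_folds <- min(cv_folds, min(table(y)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  pos <- levels(y)[2]
  score_sum <- numeric(n)
  for (rep in seq_len(cv_repeats)) {
    fold <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    for (f in seq_len(cv_folds)) {
      test <- fold == f
      rf <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                       ntree = n_trees)
      pr <- predict(rf, x[test, , drop = FALSE], type = "prob")[, pos]
      score_sum[test] <- score_sum[test] + pr
    }
  }
  scores <- score_sum / cv_repeats
  c(roc_auc(scores, y), list(scores = scores))
}

#' Spearman phenotype screen with FDR correction
#'
#' Spearman's rank correlation between every feature and every phenotype,
#' tie-corrected p-values, and Benjamini-Hochberg q-values computed across
#' the whole feature x phenotype grid.  Pairs with fewer than 4 complete
#' observations or a constant margin are reported missing.
#'
#' @param x samples x features matrix.
#' @param phen samples x phenotypes numeric data.frame or matrix, aligned
#'   with `x` (by rownames when both have them).
#' @return a `correlation_screen`: list of features x phenotypes matrices
#'   `rho`, `p`, `q`.
#' @export
spearman_screen <- function(x, phen) {
  x <- as.matrix(x)
  phen <- as.matrix(phen)
  if (!is.null(rownames(x)) && !is.null(rownames(phen))) {
    if (!setequal(rownames(x), rownames(phen)))
      stop("x and phen must cover the same samples")
    phen <- phen[rownames(x), , drop = FALSE]
  } else if (nrow(x) != nrow(phen)) stop("x and phen must be aligned")
  rho <- p <- matrix(NA_real_, ncol(x), ncol(phen),
                     dimnames = list(colnames(x), colnames(phen)))
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(phen))) {
    xi <- x[, i]; yj <- phen[, j]
    ok <- !is.na(xi) & !is.na(yj)
    if (sum(ok) < 4 || sd(xi[ok]) == 0 || sd(yj[ok]) == 0) next
    ct <- suppressWarnings(cor.test(xi[ok], yj[ok], method = "spearman",
                                    exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  q <- matrix(p.adjust(p, method = "BH"), nrow(p), ncol(p),
              dimnames = dimnames(p))
  structure(list(rho = rho, p = p, q = q), class = "correlation_screen")
}

#' @rdname spearman_screen
#' @param screen a `correlation_screen`.
#' @param path output TSV (feature, phenotype, rho, p, q).
#' @export
write_screen <- function(screen, path) {
  long <- expand.grid(feature = rownames(screen$rho),
                      phenotype = colnames(screen$rho),
                      stringsAsFactors = FALSE)
  long$rho <- as.vector(screen$rho)
  long$p <- as.vector(screen$p)
  long$q <- as.vector(screen$q)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Health-relevant feature set
#'
#' Features confirmed by the Boruta selection that also correlate with at
#' least one phenotype at `q < alpha_q`.
#'
#' @param b a `boruta_result`.
#' @param screen a `correlation_screen` on the same features.
#' @param alpha_q FDR threshold (default 0.05).
#' @return character vector of feature ids.
#' @export
health_relevant <- function(b, screen, alpha_q = 0.05) {
  confirmed <- names(b$status)[b$status == "confirmed"]
  confirmed <- intersect(confirmed, rownames(screen$q))
  sig <- rownames(screen$q)[apply(screen$q < alpha_q, 1, any, na.rm = TRUE)]
  intersect(confirmed, sig)
}
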