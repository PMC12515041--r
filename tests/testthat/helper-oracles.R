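# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops, straight from the defining formulas.

# within-subject (repeated observations) correlation, centred-sums form
oracle_rm_corr <- function(x, y, subject) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; subject <- as.character(subject)[keep]
  num <- 0; dx2 <- 0; dy2 <- 0
  for (s in unique(subject)) {
    i <- subject == s
    mx <- mean(x[i]); my <- mean(y[i])
    num <- num + sum((x[i] - mx) * (y[i] - my))
    dx2 <- dx2 + sum((x[i] - mx)^2)
    dy2 <- dy2 + sum((y[i] - my)^2)
  }
  if (dx2 == 0 || dy2 == 0) return(NA_real_)
  num / sqrt(dx2 * dy2)
}

# Kendall tau-b by explicit concordant/discordant pair counting
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  # count tied pairs by exact value equality (table() would stringify
  # doubles and merge near-ties)
  tie <- function(v) {
    s <- 0
    for (val in unique(v)) { t <- sum(v == val); s <- s + t * (t - 1) / 2 }
    s
  }
  den <- sqrt((n0 - tie(x)) * (n0 - tie(y)))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# Benjamini-Hochberg step-up, closed form; NAs are left out of the
# ranking and returned as NA
oracle_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  p <- p[ok]
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- pmin(rev(cummin(rev(q))), 1)
  out[ok[o]] <- q
  out
}

# Anderson pseudo-F straight from the group sums of squared distances
oracle_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.integer(factor(groups))
  k <- max(groups)
  ss_t <- sum(d[upper.tri(d)]^2) / n
  ss_w <- 0
  for (g in seq_len(k)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# exact two-group PERMANOVA p by full enumeration of distinct relabelings
oracle_permanova_exact <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.integer(factor(groups))
  n1 <- sum(groups == 1)
  F_obs <- oracle_pseudo_f(d, groups)
  combos <- combn(n, n1)
  if (2 * n1 == n) combos <- combos[, combos[1, ] == 1, drop = FALSE]
  Fs <- apply(combos, 2, function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    oracle_pseudo_f(d, g)
  })
  list(F = F_obs, p = mean(Fs >= F_obs - 1e-12), n = ncol(combos))
}

# naive Ward.D2 agglomeration (Lance-Williams on squared distances);
# returns the partition at every cluster count k
oracle_ward_partitions <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  size <- rep(1, n)
  member <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  parts <- list()
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- 0; bj <- 0
    for (i in which(active)) for (j in which(active)) {
      if (j <= i) next
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    for (k in which(active)) {
      if (k == bi || k == bj) next
      D2[bi, k] <- D2[k, bi] <-
        ((size[bi] + size[k]) * D2[bi, k] + (size[bj] + size[k]) * D2[bj, k] -
           size[k] * D2[bi, bj]) / (size[bi] + size[bj] + size[k])
    }
    member[[bi]] <- c(member[[bi]], member[[bj]])
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
    lab <- integer(n)
    for (ci in which(active)) lab[member[[ci]]] <- ci
    parts[[n - step]] <- lab
  }
  parts   # parts[[k]] = labels at k clusters
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# normalized mutual agreement of partitions irrespective of label names
same_partition <- function(a, b) isTRUE(all.equal(ari(a, b), 1))
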