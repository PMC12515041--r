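#' Ward hierarchical clustering of a distance matrix
#'
#' Builds the binary merge tree over features used as the scaffold for
#' co-abundance group (CAG) splitting.  The Ward.D2 criterion (squared
#' Lance-Williams update on the supplied distances) is the default; Ward.D
#' is available for comparison with older workflows.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 2 items.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an `hclust` tree; leaves are the items of `d`.
#' @export
ward_tree <- function(d, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  dd <- as.dist(d)
  if (attr(dd, "Size") < 2) stop("need at least 2 items to cluster")
  hclust(dd, method = method)
}

#' Export a tree as newick
#'
#' @param tree an `hclust` tree.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# member indices of every node of an hclust tree: negative ids are leaves,
# positive ids internal nodes (rows of tree$merge)
node_members <- function(tree) {
  m <- tree$merge
  out <- vector("list", nrow(m))
  get <- function(id) if (id < 0) -id else out[[id]]
  for (i in seq_len(nrow(m))) out[[i]] <- c(get(m[i, 1]), get(m[i, 2]))
  out
}

# distinct two-group relabelings of n items into sizes (n1, n - n1)
n_distinct_relabelings <- function(n, n1) {
  N <- choose(n, n1)
  if (2 * n1 == n) N <- N / 2
  N
}

# two-group PERMANOVA pseudo-F from a squared-distance matrix
two_group_pseudo_f <- function(D2, grp) {
  n <- nrow(D2)
  ss_t <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in unique(grp)) {
    s <- grp == g
    ssw <- ssw + sum(D2[s, s]) / (2 * sum(s))
  }
  (ss_t - ssw) / (ssw / (n - 2))
}

# sum over groups of within-group squared-distance terms, for a block of
# label vectors at once (columns of L)
ssw_block <- function(D2, L, sizes) {
  ssw <- numeric(ncol(L))
  for (g in seq_along(sizes)) {
    Z <- (L == g) * 1
    ssw <- ssw + colSums(Z * (D2 %*% Z)) / (2 * sizes[g])
  }
  ssw
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in Anderson's
#' formulation: with total sum of squares
#' \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and within-group
#' \eqn{SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g}, the pseudo-F is
#' \eqn{F = ((SS_T - SS_W)/(k-1)) / (SS_W/(n-k))}.  The p-value is the
#' permutation tail probability `(1 + #[F* >= F]) / (1 + n_perm)`.  For two
#' groups, when the number of distinct relabelings (`choose(n, n1)`,
#' halved for equal sizes) does not exceed `n_perm`, every relabeling is
#' enumerated instead of sampled and the p-value is the exact fraction of
#' relabelings (observed included) with `F* >= F`.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups group labels, length = number of items; >= 2 groups, no
#'   group equal to the full set.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional seed for the permutation stream.
#' @return list with `F`, `p`, `n_perm` (permutations actually used),
#'   `exhaustive`, and `n_distinct` (two-group relabeling count).
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must match the distance matrix size")
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups (no group may equal the full set)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  D2 <- D^2
  sizes <- as.integer(table(groups))
  gl <- as.integer(groups)
  ss_t <- sum(D2) / (2 * n)
  fstat <- function(lab) {
    ssw <- 0
    for (g in seq_len(k)) {
      idx <- lab == g
      ssw <- ssw + sum(D2[idx, idx]) / (2 * sizes[g])
    }
    ((ss_t - ssw) / (k - 1)) / (ssw / (n - k))
  }
  F_obs <- fstat(gl)
  eps <- 1e-12
  n_distinct <- if (k == 2) n_distinct_relabelings(n, sizes[1]) else NA_real_
  if (k == 2 && n_distinct <= n_perm) {
    combos <- combn(n, sizes[1])
    if (2 * sizes[1] == n) combos <- combos[, combos[1, ] == 1, drop = FALSE]
    L <- matrix(2L, n, ncol(combos))
    for (j in seq_len(ncol(combos))) L[combos[, j], j] <- 1L
    ssw <- ssw_block(D2, L, sizes)
    Fs <- ((ss_t - ssw) / (k - 1)) / (ssw / (n - k))
    p <- sum(Fs >= F_obs - eps) / ncol(combos)
    return(list(F = F_obs, p = p, n_perm = ncol(combos),
                exhaustive = TRUE, n_distinct = n_distinct))
  }
  exceed <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    L <- vapply(seq_len(b), function(i) gl[sample.int(n)], integer(n))
    ssw <- ssw_block(D2, L, sizes)
    Fs <- ((ss_t - ssw) / (k - 1)) / (ssw / (n - k))
    exceed <- exceed + sum(Fs >= F_obs - eps)
    done <- done + b
  }
  list(F = F_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
       exhaustive = FALSE, n_distinct = n_distinct)
}

# selection-aware split test: the two child clades were chosen by Ward on
# these very distances, so a plain label-permutation null is degenerate
# (the observed F is by construction an extreme of it).  The null here
# shuffles the off-diagonal distances of the node's submatrix, re-runs
# Ward within the node and scores the re-selected two-way split, making
# observed and permuted F exchangeable when the node's distances carry no
# structure.  Permutations stop early once the exceedance count rules out
# p < alpha.
split_test_ward_null <- function(D, grp, alpha, n_perm, method) {
  n <- nrow(D)
  F_obs <- two_group_pseudo_f(D^2, grp)
  ut <- upper.tri(D)
  v <- D[ut]
  max_exceed <- alpha * (1 + n_perm) - 1   # still compatible with p < alpha
  exceed <- 0L
  done <- 0L
  for (i in seq_len(n_perm)) {
    Dp <- matrix(0, n, n)
    Dp[ut] <- sample(v)
    Dp <- Dp + t(Dp)
    hc <- hclust(as.dist(Dp), method = method)
    lab <- cutree(hc, 2)
    done <- i
    # the re-selected split is scored on the permuted distances
    if (two_group_pseudo_f(Dp^2, lab) >= F_obs - 1e-12) {
      exceed <- exceed + 1L
      if (exceed > max_exceed) break
    }
  }
  list(F = F_obs, p = (1 + exceed) / (1 + done), n_perm = done)
}

#' Split a Ward tree into co-abundance groups by consecutive PERMANOVA
#'
#' Walks the tree depth-first from the root.  At each internal node the two
#' child clades define a two-group PERMANOVA pseudo-F on the correlation
#' distance restricted to the node's members; if `p < alpha` the split is
#' accepted and each child is examined in turn, otherwise the node's
#' member set becomes one CAG.  Leaves reached through accepted splits
#' become singleton CAGs.  Untestable nodes (too few members for the
#' permutation floor to pass `alpha`) are declared CAGs without testing
#' (decision `"untestable"`).
#'
#' Because the candidate split is itself selected by Ward clustering of
#' the tested distances, a naive fixed-split label permutation
#' (`split_null = "labels"`, the null of [permanova()]) is
#' anti-conservative at every node — the observed F is by construction an
#' extreme of it — and is retained only for comparison.  The calibrated
#' nulls re-select the split per permutation: `"data"` (default whenever
#' the rCLR matrix is supplied) permutes each feature's values
#' independently across samples, recomputes the repeated-observations
#' correlation distance among the node's members and re-runs Ward,
#' destroying co-abundance while preserving each feature's marginal
#' distribution and missingness; `"ward"` (default for distance-only
#' input) shuffles the node's off-diagonal distances and re-runs Ward,
#' exact when the distances themselves are exchangeable.
#'
#' @param tree `hclust` tree from [ward_tree()].
#' @param d the distance matrix the tree was built on.
#' @param alpha per-split significance cutoff, in (0, 1); default 0.001.
#' @param n_perm permutations per test (default 9999); must exceed
#'   `1/alpha - 1` for any split to be acceptable.
#' @param seed optional seed making the whole walk reproducible.
#' @param table optional count table; when supplied, CAGs are labelled
#'   CAG1, CAG2, ... in decreasing mean abundance, otherwise in tree
#'   order.
#' @param data rCLR matrix (samples x features, `NA` = missing) the
#'   correlations were computed from; enables the `"data"` null.
#' @param meta sample metadata with `sample_id` and `subject_id`,
#'   required with `data`.
#' @param split_null `"data"`, `"ward"` or `"labels"`; default `"data"`
#'   when `data` is supplied, else `"ward"`.
#' @param linkage linkage criterion used when re-clustering permuted
#'   distances; matches [ward_tree()]'s default.
#' @param min_split_n smallest node size still tested under the
#'   re-selection nulls; smaller nodes become CAGs untested (default 5).
#' @return a `cag_assignment`: list with `assignment` (named character
#'   vector, feature -> CAG label), `splits` (one row per examined node:
#'   node id, size, F, p, permutations, decision) and the call parameters.
#' @export
split_cags <- function(tree, d, alpha = 0.001, n_perm = 9999, seed = NULL,
                       table = NULL, data = NULL, meta = NULL,
                       split_null = NULL, linkage = "ward.D2",
                       min_split_n = 5) {
  if (is.null(split_null))
    split_null <- if (is.null(data)) "ward" else "data"
  split_null <- match.arg(split_null, c("data", "ward", "labels"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  D <- as.matrix(d)
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(D)))
  if (nrow(D) != length(labs)) stop("tree and distance matrix disagree")
  subj <- NULL
  pair_rows <- NULL
  if (split_null == "data") {
    if (is.null(data) || is.null(meta))
      stop("split_null = 'data' needs the rCLR matrix and metadata")
    if (!all(labs %in% colnames(data)))
      stop("data must contain a column for every clustered feature")
    midx <- match(rownames(data), meta$sample_id)
    if (anyNA(midx)) stop("every sample in data needs a metadata row")
    subj <- as.integer(factor(meta$subject_id[midx])) - 1L
    # exact BLAS shortcut for the paired (<= 2 observations/subject) design
    rows_by_subj <- split(seq_along(subj) - 1L, subj)
    if (max(lengths(rows_by_subj)) <= 2) {
      two <- rows_by_subj[lengths(rows_by_subj) == 2]
      if (length(two) >= 2)
        pair_rows <- matrix(unlist(two), nrow = 2)
    }
  }
  if (1 / (n_perm + 1) >= alpha)
    warning("n_perm too small for any split to reach p < alpha; one CAG")
  if (!is.null(seed)) set.seed(seed)
  members <- node_members(tree)
  splits <- list()
  cags <- list()
  walk <- function(id) {
    if (id < 0) { cags[[length(cags) + 1]] <<- -id; return(invisible()) }
    ch <- tree$merge[id, ]
    a <- if (ch[1] < 0) -ch[1] else members[[ch[1]]]
    b <- if (ch[2] < 0) -ch[2] else members[[ch[2]]]
    idx <- c(a, b)
    n1 <- length(a)
    nn <- length(idx)
    # testability: the fixed-split null is floored by the relabeling
    # count; the re-selection nulls by node size
    untestable <- if (split_null == "labels")
      n_distinct_relabelings(nn, n1) < 1 / alpha else nn < min_split_n
    if (untestable || 1 / (n_perm + 1) >= alpha) {
      splits[[length(splits) + 1]] <<- data.frame(
        node = id, n = nn, F = NA_real_, p = NA_real_,
        n_perm = 0L, decision = "untestable")
      cags[[length(cags) + 1]] <<- idx
      return(invisible())
    }
    grp <- rep(1:2, c(length(a), length(b)))
    pv <- switch(split_null,
      data = {
        Dn <- D[idx, idx, drop = FALSE]
        f_obs <- two_group_pseudo_f(Dn^2, grp)
        .split_test_data_cpp(data[, labs[idx], drop = FALSE], subj,
                             max(subj) + 1L, f_obs, alpha, n_perm,
                             pair_rows)
        },
      ward = split_test_ward_null(D[idx, idx, drop = FALSE], grp, alpha,
                                  n_perm, linkage),
      labels = permanova(D[idx, idx, drop = FALSE], grp, n_perm = n_perm))
    if (is.null(pv$F)) pv$F <- two_group_pseudo_f(D[idx, idx]^2, grp)
    accept <- pv$p < alpha
    splits[[length(splits) + 1]] <<- data.frame(
      node = id, n = length(idx), F = pv$F, p = pv$p,
      n_perm = pv$n_perm, decision = if (accept) "split" else "cag")
    if (accept) { walk(ch[1]); walk(ch[2]) } else
      cags[[length(cags) + 1]] <<- idx
    invisible()
  }
  walk(nrow(tree$merge))
  if (!is.null(table)) {
    ab <- vapply(cags, function(idx)
      mean(rowSums(table[, labs[idx], drop = FALSE])), numeric(1))
    cags <- cags[order(ab, decreasing = TRUE)]
  }
  assignment <- character(length(labs))
  names(assignment) <- labs
  for (i in seq_along(cags)) assignment[labs[cags[[i]]]] <- sprintf("CAG%d", i)
  structure(list(assignment = assignment,
                 splits = do.call(rbind, splits),
                 alpha = alpha, n_perm = n_perm),
            class = "cag_assignment")
}

#' @export
print.cag_assignment <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("cag_assignment: %d features in %d CAGs (alpha = %g)\n",
              length(x$assignment), k, x$alpha))
  tested <- x$splits
  cat(sprintf("  %d nodes examined: %d split, %d kept, %d untestable\n",
              nrow(tested), sum(tested$decision == "split"),
              sum(tested$decision == "cag"),
              sum(tested$decision == "untestable")))
  invisible(x)
}

#' @rdname split_cags
#' @param a a `cag_assignment`.
#' @param path output TSV (feature-id, CAG).
#' @export
write_cag_assignment <- function(a, path) {
  write.table(data.frame(`feature-id` = names(a$assignment),
                         CAG = unname(a$assignment), check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' CAG abundance table
#'
#' The abundance of a CAG in a sample is the sum of its member features'
#' values; read totals of the assigned features are conserved exactly.
#'
#' @param table feature table covering the assigned features (extra
#'   features are ignored).
#' @param a `cag_assignment` (or a named feature -> label vector).
#' @return samples x CAGs feature table, columns in CAG label order.
#' @export
cag_abundance <- function(table, a) {
  map <- if (inherits(a, "cag_assignment")) a$assignment else a
  feats <- intersect(colnames(table), names(map))
  if (length(feats) == 0) stop("no assigned feature present in the table")
  lab <- map[feats]
  labels <- unique(lab)
  num <- suppressWarnings(as.integer(sub("^CAG", "", labels)))
  labels <- if (!anyNA(num)) labels[order(num)] else sort(labels)
  out <- vapply(labels, function(L)
    rowSums(table[, feats[lab == L], drop = FALSE]), numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), labels))
  out
}

#' Co-abundance network edge list
#'
#' Feature-level edges keep pairs with `|r|` strictly above `min_abs`;
#' CAG-level edges carry the mean correlation over all inter-CAG feature
#' pairs, thresholded the same way.  Node annotations give each CAG's mean
#' relative abundance; CAGs at or below `min_mean_abund` are flagged
#' `hidden` (the display convention "mean abundance > 1% shown").
#'
#' @param r feature correlation matrix.
#' @param a `cag_assignment`.
#' @param min_abs minimum absolute correlation, strict (default 0.5).
#' @param min_mean_abund minimum mean relative abundance for a visible CAG
#'   node (default 0.01).
#' @param table count table used for the abundance annotation.
#' @return list with data.frames `feature_edges` (a, b, r, sign),
#'   `cag_edges` (cag_a, cag_b, r, sign) and `nodes` (cag, mean_rel_abund,
#'   hidden).
#' @export
network_edges <- function(r, a, min_abs = 0.5, min_mean_abund = 0.01, table) {
  map <- if (inherits(a, "cag_assignment")) a$assignment else a
  feats <- intersect(rownames(r), names(map))
  rr <- r[feats, feats, drop = FALSE]
  ut <- which(upper.tri(rr) & abs(rr) > min_abs, arr.ind = TRUE)
  fe <- data.frame(a = feats[ut[, 1]], b = feats[ut[, 2]],
                   r = rr[ut], sign = ifelse(rr[ut] > 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  lab <- map[feats]
  labels <- sort(unique(lab))
  ce <- list()
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    if (j <= i) next
    block <- rr[lab == labels[i], lab == labels[j], drop = FALSE]
    mr <- mean(block)
    if (abs(mr) > min_abs)
      ce[[length(ce) + 1]] <- data.frame(
        cag_a = labels[i], cag_b = labels[j], r = mr,
        sign = ifelse(mr > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
  }
  ce <- if (length(ce)) do.call(rbind, ce) else
    data.frame(cag_a = character(), cag_b = character(),
               r = numeric(), sign = character())
  rel <- table[, feats, drop = FALSE] / rowSums(table)
  ab <- vapply(labels, function(L)
    mean(rowSums(rel[, lab == L, drop = FALSE])), numeric(1))
  nodes <- data.frame(cag = labels, mean_rel_abund = ab,
                      hidden = !(ab > min_mean_abund),
                      stringsAsFactors = FALSE)
  list(feature_edges = fe, cag_edges = ce, nodes = nodes)
}
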