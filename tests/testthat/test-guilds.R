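test_that("ward_tree merges planted pairs first and matches the naive oracle", {
  # two tight pairs far apart: first two merges are the pairs
  d <- rbind(c(0, 0.1, 1.9, 1.8),
             c(0.1, 0, 1.85, 1.9),
             c(1.9, 1.85, 0, 0.1),
             c(1.8, 1.9, 0.1, 0))
  dimnames(d) <- list(paste0("f", 1:4), paste0("f", 1:4))
  tr <- ward_tree(d)
  first_two <- lapply(1:2, function(i) sort(-tr$merge[i, ]))
  expect_setequal(lapply(first_two, paste, collapse = ","), c("1,2", "3,4"))
  # identical rows merge at height zero
  d0 <- rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0))
  dimnames(d0) <- list(paste0("f", 1:3), paste0("f", 1:3))
  expect_equal(ward_tree(d0)$height[1], 0)
  expect_error(ward_tree(matrix(0, 1, 1)), "at least 2")
})

test_that("ward_tree partitions equal a naive Lance-Williams implementation", {
  set.seed(8)
  d <- iid_distance(10)
  tr <- ward_tree(d)
  parts <- oracle_ward_partitions(d)
  for (k in 2:9)
    expect_true(same_partition(cutree(tr, k), parts[[k]]))
})

test_that("permanova F matches the oracle and vegan, and p the exact enumeration", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    d <- iid_distance(n)
    g <- rep(1:2, c(2, n - 2))
    res <- permanova(d, g, n_perm = 9999)
    exact <- oracle_permanova_exact(d, g)
    expect_equal(res$F, exact$F, tolerance = 1e-10)
    expect_true(res$exhaustive)
    expect_equal(res$p, exact$p, tolerance = 1e-12)
  }
  # n=4 balanced: p is a multiple of 1/3 over the 3 distinct splits
  d4 <- iid_distance(4)
  p4 <- permanova(d4, c(1, 1, 2, 2), n_perm = 9999)$p
  expect_true(any(abs(p4 - c(1, 2, 3) / 3) < 1e-12))
  # cross-check F against vegan::adonis2 on a sample x feature layout
  set.seed(9)
  x <- matrix(abs(rnorm(60)), 10, 6)
  dd <- as.matrix(vegan::vegdist(x, "euclidean"))
  grp <- rep(c("a", "b"), each = 5)
  f_vegan <- vegan::adonis2(as.dist(dd) ~ grp, permutations = 2)$F[1]
  expect_equal(permanova(dd, grp, n_perm = 9)$F, f_vegan, tolerance = 1e-8)
})

test_that("permanova F is invariant to relabeling items within groups", {
  set.seed(10)
  d <- iid_distance(9)
  g <- rep(1:3, each = 3)
  F1 <- permanova(d, g, n_perm = 9)$F
  perm <- c(2, 3, 1, 6, 4, 5, 9, 7, 8)  # permutes within each group
  F2 <- permanova(d[perm, perm], g, n_perm = 9)$F
  expect_equal(F1, F2, tolerance = 1e-12)
  expect_error(permanova(d, rep(1, 9)), "2 groups")
})

test_that("split_cags recovers planted distance blocks and respects alpha limits", {
  set.seed(12)
  d <- block_distance(c(15, 15))
  tr <- ward_tree(d)
  ca <- split_cags(tr, d, alpha = 0.001, n_perm = 1999, seed = 1)
  expect_equal(length(unique(ca$assignment)), 2)
  expect_true(same_partition(ca$assignment, attr(d, "blocks")))
  # n_perm below the alpha floor cannot split anything
  expect_warning(ca1 <- split_cags(tr, d, alpha = 0.001, n_perm = 500, seed = 1),
                 "n_perm too small")
  expect_equal(length(unique(ca1$assignment)), 1)
  expect_error(split_cags(tr, d, alpha = 2), "alpha")
})

test_that("split_cags is deterministic given a seed and labels by abundance", {
  set.seed(13)
  d <- block_distance(c(8, 8))
  tab <- tiny_table(matrix(rpois(10 * 16, 5), 10, 16),
                    features = rownames(d))
  tab[, 9:16] <- tab[, 9:16] * 20   # second block far more abundant
  tr <- ward_tree(d)
  ca1 <- split_cags(tr, d, n_perm = 1999, seed = 7, table = tab)
  ca2 <- split_cags(tr, d, n_perm = 1999, seed = 7, table = tab)
  expect_identical(ca1$assignment, ca2$assignment)
  expect_identical(ca1$splits, ca2$splits)
  # CAG1 is the most abundant group
  expect_true(all(ca1$assignment[rownames(d)[9:16]] == "CAG1"))
})

test_that("cag_abundance conserves reads and handles degenerate partitions", {
  set.seed(14)
  tab <- tiny_table(matrix(rpois(5 * 6, 10), 5, 6))
  one <- setNames(rep("CAG1", 6), colnames(tab))
  all_in_one <- cag_abundance(tab, one)
  expect_equal(unname(all_in_one[, 1]), unname(rowSums(tab)))
  singletons <- setNames(paste0("CAG", 1:6), colnames(tab))
  perm <- cag_abundance(tab, singletons)
  expect_equal(unname(perm), unname(tab))
  # conservation on a partial assignment
  part <- setNames(c("CAG1", "CAG1", "CAG2"), colnames(tab)[1:3])
  agg <- cag_abundance(tab, part)
  expect_identical(rowSums(agg), rowSums(tab[, 1:3]))
  expect_error(cag_abundance(tab, setNames("CAG1", "absent")), "no assigned")
})

test_that("network_edges applies strict thresholds and finds no cross-block edges", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.5    # exactly at the threshold: dropped
  r[3, 4] <- r[4, 3] <- 0.8
  dimnames(r) <- list(paste0("f", 1:4), paste0("f", 1:4))
  a <- setNames(c("CAG1", "CAG1", "CAG2", "CAG2"), rownames(r))
  tab <- tiny_table(matrix(5, 3, 4), features = rownames(r))
  net <- network_edges(r, a, min_abs = 0.5, min_mean_abund = 0.01, table = tab)
  expect_equal(nrow(net$feature_edges), 1)
  expect_setequal(c(net$feature_edges$a, net$feature_edges$b), c("f3", "f4"))
  # min_abs = 1 keeps only exact duplicates
  net1 <- network_edges(r, a, min_abs = 1, table = tab)
  expect_equal(nrow(net1$feature_edges), 0)
  # planted block structure: no spurious positive co-abundance between
  # blocks above 0.5 (compositional closure can produce negative
  # cross-block correlations, which are real, not spurious)
  set.seed(15)
  cfg <- recovery_cfg(60, 4, 15, 0.7)
  sim <- simulate_community(cfg, seed = 3)
  rc <- rclr(prevalence_filter(sim$table, 0.25))
  rr <- suppressMessages(correlation_matrix(rc, sim$metadata))
  blk <- sim$truth$block[rownames(rr)]
  amap <- setNames(paste0("CAG", as.integer(factor(blk))), rownames(rr))
  net2 <- network_edges(rr, amap, min_abs = 0.5, table = sim$table)
  cross_pos <- blk[net2$feature_edges$a] != blk[net2$feature_edges$b] &
    net2$feature_edges$r > 0
  expect_equal(sum(cross_pos, na.rm = TRUE), 0)
  # and plenty of within-block edges found
  expect_gt(nrow(net2$feature_edges), 10)
})

test_that("newick export writes a tree ape can parse back", {
  set.seed(16)
  d <- iid_distance(6)
  tr <- ward_tree(d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, rownames(d))
})
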