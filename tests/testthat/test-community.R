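test_that("alpha diversity matches closed forms", {
  tab <- tiny_table(rbind(c(5, 5, 5, 5), c(9, 0, 0, 0), c(1, 1, 2, 0)))
  ad <- alpha_diversity(tab)
  expect_equal(ad$shannon, c(2, 0, 1.5))
  expect_equal(ad$observed, c(4L, 1L, 3L))
  # natural-log option
  expect_equal(alpha_diversity(tab, base = exp(1))$shannon[1], log(4))
  expect_error(alpha_diversity(tiny_table(rbind(c(1, 1), c(0, 0)))), "zero-sum")
})

test_that("bray_curtis matches closed forms and a reference implementation", {
  tab <- tiny_table(rbind(c(2, 2, 0), c(0, 2, 2), c(2, 2, 0)))
  d <- bray_curtis(tab)
  expect_equal(d[1, 2], 0.5)
  expect_equal(d[1, 3], 0)
  disjoint <- tiny_table(rbind(c(3, 0), c(0, 7)))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  set.seed(18)
  rnd <- tiny_table(matrix(rpois(60, 8) + 1, 6, 10))
  manual <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    sum(abs(rnd[i, ] - rnd[j, ])) / sum(rnd[i, ] + rnd[j, ])))
  expect_true(max(abs(bray_curtis(rnd) - manual)) < 1e-9)
})

test_that("pcoa reconstructs Euclidean configurations and flags negatives", {
  set.seed(19)
  pts <- cbind(rnorm(8), rnorm(8))
  rownames(pts) <- paste0("S", 1:8)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_true(max(abs(rec - d)) < 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  # agreement with ape's implementation on the leading eigenvalues
  ref <- ape::pcoa(d)
  k <- ncol(ord$coordinates)
  expect_equal(ord$eigenvalues[1:k], ref$values$Eigenvalues[1:k],
               tolerance = 1e-8)
  # duplicated sample lands on identical coordinates
  d2 <- as.matrix(dist(pts[c(1, 1:8), ]))
  rownames(d2) <- colnames(d2) <- paste0("S", 0:8)
  ord2 <- pcoa(d2)
  expect_equal(ord2$coordinates["S0", ], ord2$coordinates["S1", ],
               tolerance = 1e-9)
  # three collinear points: a single positive axis
  d3 <- as.matrix(dist(cbind(c(0, 1, 3))))
  rownames(d3) <- colnames(d3) <- paste0("S", 1:3)
  ord3 <- pcoa(d3)
  expect_equal(ncol(ord3$coordinates), 1)
  expect_true(max(abs(as.matrix(dist(ord3$coordinates)) - d3)) < 1e-9)
})

test_that("pairwise PERMANOVA applies BH across pairs", {
  set.seed(20)
  x <- tiny_table(matrix(rpois(20 * 5, 10) + 1, 20, 5))
  d <- bray_curtis(x)
  g <- rep(c("a", "b", "c", "d"), each = 5)
  res <- permanova_pairwise(d, g, n_perm = 99, seed = 1)
  expect_equal(nrow(res), 6)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
  expect_true(all(res$q[order(res$p)] == cummax(res$q[order(res$p)])))
  # a single pair adjusts to itself
  one <- permanova_pairwise(d[1:10, 1:10], g[1:10], n_perm = 99, seed = 1)
  expect_equal(one$q, one$p)
})

test_that("procrustes is invariant to rotation+scaling and floors its p-value", {
  set.seed(21)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("S", 1:20), NULL))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- 3.2 * x %*% rot + 5
  oa <- list(coordinates = x)
  ob <- list(coordinates = y)
  pr <- procrustes_compare(oa, ob, n_perm = 199, seed = 2)
  expect_lt(pr$m12_squared, 1e-9)
  expect_equal(pr$protest_p, 1 / 200)
  # symmetric in its arguments
  set.seed(3)
  z <- matrix(rnorm(40), 20, 2, dimnames = dimnames(x))
  f <- procrustes_compare(oa, list(coordinates = z), n_perm = 49, seed = 4)
  b <- procrustes_compare(list(coordinates = z), oa, n_perm = 49, seed = 4)
  expect_equal(f$m12_squared, b$m12_squared, tolerance = 1e-9)
  expect_error(procrustes_compare(oa, list(coordinates = z[1:10, ])),
               "same samples")
})

test_that("information loss is the m12^2 ratio with an undefined marker at 0", {
  expect_equal(information_loss(0.4, 0.2), 2)
  expect_equal(information_loss(0.3, 0.3), 1)
  suppressMessages(u <- information_loss(0.3, 0))
  expect_true(is.na(u))
  expect_true(attr(u, "undefined"))
  expect_error(information_loss(-0.1, 0.2), "negative")
})

test_that("ordination writer emits the eigvals/proportion/site layout", {
  set.seed(22)
  ord <- pcoa(as.matrix(dist(matrix(rnorm(12), 6, 2,
                                    dimnames = list(paste0("S", 1:6), NULL)))))
  f <- withr::local_tempfile(fileext = ".txt")
  write_ordination(ord, f)
  lines <- readLines(f)
  expect_match(lines[1], "^Eigvals")
  expect_match(lines[4], "^Proportion explained")
  expect_match(lines[7], "^Site")
})
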