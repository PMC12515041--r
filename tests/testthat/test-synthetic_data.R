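test_that("the generator is deterministic and respects its contracts", {
  cfg <- sim_config(n_subjects = 12, n_features = 50, n_blocks = 4,
                    features_per_block = 8, depth = 4000,
                    sparsity_target = NULL)
  a <- simulate_community(cfg, seed = 42)
  b <- simulate_community(cfg, seed = 42)
  expect_identical(a, b)
  expect_true(all(rowSums(a$table) == cfg$depth))
  expect_silent(validate_feature_table(a$table))
  expect_equal(nrow(a$metadata), 24)
  expect_equal(anyDuplicated(a$metadata$sample_id), 0)
  # every feature has a taxonomy row
  expect_setequal(a$taxonomy$feature_id, colnames(a$table))
  expect_error(sim_config(nonsense = 1), "unknown")
})

test_that("the sparsity dropout lands near its target or errors when infeasible", {
  cfg <- sim_config(n_subjects = 12, n_features = 80, n_blocks = 4,
                    features_per_block = 8, depth = 6000,
                    sparsity_target = 0.7)
  sim <- simulate_community(cfg, seed = 2)
  expect_lt(abs(sparsity(sim$table) / 100 - 0.7), 0.05)
  # a dropout can only add zeros: a target below the sampling sparsity is
  # infeasible
  sparse <- sim_config(n_subjects = 6, n_features = 400, n_blocks = 2,
                       features_per_block = 5, depth = 200,
                       base_mean_bg = -4, sparsity_target = 0.01)
  expect_error(simulate_community(sparse, seed = 1), "infeasible")
})

test_that("unclassifiable taxonomy share tracks the configured fraction", {
  cfg <- sim_config(n_subjects = 15, n_features = 200, n_blocks = 10,
                    features_per_block = 10, depth = 15000,
                    sparsity_target = NULL, unclassifiable_fraction = 0.2)
  shares <- sapply(1:5, function(s) {
    sim <- simulate_community(cfg, seed = s)
    aggregate_genus(sim$table, sim$taxonomy)$excluded_read_fraction
  })
  expect_true(all(abs(shares - 0.2) < 0.03))
  # and the excluded set is exactly the planted unclassifiable features
  sim <- simulate_community(cfg, seed = 1)
  res <- aggregate_genus(sim$table, sim$taxonomy)
  expect_setequal(res$excluded, sim$truth$unclassifiable)
})

test_that("within-block correlation vanishes when no structure is planted", {
  deltas <- sapply(1:5, function(s) {
    cfg <- sim_config(n_subjects = 25, n_features = 40, n_blocks = 4,
                      features_per_block = 10, within_block_corr = 0,
                      sparsity_target = NULL, depth = 15000,
                      block_effects = NULL)
    sim <- simulate_community(cfg, seed = 100 + s)
    rc <- rclr(prevalence_filter(sim$table, 0.25))
    r <- suppressMessages(correlation_matrix(rc, sim$metadata))
    blk <- sim$truth$block[rownames(r)]
    same <- outer(blk, blk, "==")[upper.tri(r)]
    vals <- r[upper.tri(r)]
    mean(vals[same], na.rm = TRUE) - mean(vals[!same], na.rm = TRUE)
  })
  expect_true(all(abs(deltas) < 0.05))
})

test_that("timecourse modulation is rhythmic only where planted", {
  cfg <- sim_config(n_subjects = 8, n_features = 30, n_blocks = 3,
                    features_per_block = 10, within_block_corr = 0.6,
                    sparsity_target = NULL, depth = 8000,
                    timecourse_replicates = 3,
                    rhythmic_blocks = data.frame(block = "B1", amplitude = 2,
                                                 phase = 14))
  tc <- simulate_timecourse(cfg, seed = 7)
  expect_true(all(rowSums(tc$table) == cfg$depth))
  expect_equal(nrow(tc$metadata), 8 * 3)
  blocks <- sapply(paste0("B", 1:3), function(b)
    rowSums(tc$table[, names(tc$truth$block)[!is.na(tc$truth$block) &
                                               tc$truth$block == b]]))
  rel <- blocks / rowSums(tc$table)
  set.seed(8)
  p_rhy <- ejtk(rel[, "B1"], tc$metadata$zt_hours, n_perm = 499)$empirical_p
  expect_lt(p_rhy, 0.05)
  # a fully flat community (no rhythm planted anywhere) shows none; note
  # that in the planted community the closure makes OTHER blocks' relative
  # abundances anti-oscillate, which is real, not a false positive
  flat <- simulate_timecourse(cfg, seed = 7, rhythmic = NULL)
  relf <- sapply(paste0("B", 1:3), function(b)
    rowSums(flat$table[, names(flat$truth$block)[!is.na(flat$truth$block) &
                                                   flat$truth$block == b]])) /
    rowSums(flat$table)
  set.seed(9)
  p_null <- ejtk(relf[, "B3"], flat$metadata$zt_hours, n_perm = 499)$empirical_p
  expect_gt(p_null, 0.05)
  expect_error(simulate_timecourse(cfg, rhythmic = data.frame(
    block = "B1", amplitude = -1, phase = 0)), "negative")
  expect_error(simulate_timecourse(cfg, rhythmic = data.frame(
    block = "B99", amplitude = 1, phase = 0)), "outside")
})

test_that("null phenotypes yield a null Spearman screen", {
  cfg <- sim_config(n_subjects = 25, n_features = 40, n_blocks = 4,
                    features_per_block = 10, sparsity_target = NULL,
                    depth = 10000,
                    phenotype_model = list(
                      flat = list(intercept = 100, noise_sd = 5, beta = NULL)))
  sim <- simulate_community(cfg, seed = 3)
  ph <- simulate_phenotypes(sim$truth, sim$table, cfg, seed = 4)
  x <- sim$table / rowSums(sim$table)
  sc <- spearman_screen(x, matrix(ph$flat, ncol = 1,
                                  dimnames = list(ph$sample_id, "flat")))
  expect_gt(min(sc$q, na.rm = TRUE), 0.05)
  expect_error(simulate_phenotypes(sim$truth, sim$table,
                                   utils::modifyList(cfg, list(phenotype_model =
                                     list(bad = list(intercept = 0, noise_sd = 1,
                                                     beta = c(B99 = 1))))),
                                   seed = 1), "unknown or absent")
})

test_that("two phenotypes sharing a block carry consistent signs", {
  cfg <- sim_config(n_subjects = 30, n_features = 40, n_blocks = 4,
                    features_per_block = 10, sparsity_target = NULL,
                    depth = 10000,
                    phenotype_model = list(
                      p1 = list(intercept = 0, noise_sd = 0.5, beta = c(B2 = 100)),
                      p2 = list(intercept = 0, noise_sd = 0.5, beta = c(B2 = 100))))
  sim <- simulate_community(cfg, seed = 6)
  ph <- simulate_phenotypes(sim$truth, sim$table, cfg, seed = 7)
  expect_gt(cor(ph$p1, ph$p2, method = "spearman"), 0)
})

test_that("trapezoid_auc integrates glucose curves", {
  expect_equal(trapezoid_auc(c(5, 10, 5), c(0, 15, 30)), 225)
  expect_equal(trapezoid_auc(rep(7, 5), c(0, 15, 30, 60, 120)), 7 * 120)
  expect_equal(trapezoid_auc(c(3, 9), c(10, 20)), 10 * 6)
  expect_error(trapezoid_auc(c(1, 2), c(5, 5)), "increasing")
  expect_error(trapezoid_auc(1, 1), ">= 2")
})
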