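test_that("reference waveforms deduplicate phases and cover both directions", {
  zt <- seq(0, 42, by = 6)
  refs <- reference_waveforms(zt, period = 24, phase_step = 6)
  expect_lte(ncol(refs), 4)
  phases <- attr(refs, "phases")
  # a phase one full period later is the same pattern
  refs2 <- reference_waveforms(zt, period = 24, phase_step = 3)
  pat <- apply(refs2, 2, rank)
  expect_equal(anyDuplicated(t(pat)), 0)
  # antiphase references are rank-reversed: perfect negative concordance
  # (rounded so that mathematically-tied cosine values tie exactly)
  r0 <- round(cos(2 * pi * zt / 24), 9)
  r12 <- round(cos(2 * pi * (zt - 12) / 24), 9)
  expect_equal(jtk_statistic(r0, r12), -1)
  expect_error(reference_waveforms(c(0, 6), 24), "3 distinct")
})

test_that("jtk statistic equals tau-b from the pair-count oracle", {
  zt <- seq(0, 42, by = 6)
  ref <- cos(2 * pi * (zt - 6) / 24)
  expect_equal(jtk_statistic(ref, ref), 1)
  expect_equal(jtk_statistic(-ref, ref), -1)
  set.seed(23)
  for (i in 1:10) {
    s <- sample(rpois(8, 4))   # ties included
    expect_equal(jtk_statistic(s, ref), oracle_kendall(s, ref),
                 tolerance = 1e-12)
  }
  # stats::cor cross-check
  s <- rnorm(8)
  expect_equal(jtk_statistic(s, ref), cor(s, ref, method = "kendall"),
               tolerance = 1e-12)
  flat <- jtk_statistic(rep(2, 8), ref)
  expect_equal(unname(c(flat)), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("ejtk detects planted cosines, recovers phase and floors p", {
  zt <- rep(seq(0, 42, by = 6), each = 3)   # 8 timepoints x 3 replicates
  set.seed(24)
  hits <- replicate(10, {
    s <- cos(2 * pi * (zt - 14) / 24) + rnorm(length(zt), 0, 0.3)
    r <- ejtk(s, zt, n_perm = 999)
    c(p = r$empirical_p, phase = r$best_phase)
  })
  expect_true(all(hits["p", ] <= 0.005))
  phase_err <- pmin(abs(hits["phase", ] - 14), 24 - abs(hits["phase", ] - 14))
  expect_true(all(phase_err <= 3))
  # constant series
  r0 <- ejtk(rep(1, length(zt)), zt, n_perm = 199)
  expect_equal(r0$empirical_p, 1)
  # p never under the permutation floor
  expect_gte(min(hits["p", ]), 1 / 1000)
})

test_that("ejtk p-values are invariant to strictly monotone transforms", {
  zt <- rep(seq(0, 42, by = 6), each = 3)
  set.seed(25)
  s <- cos(2 * pi * zt / 24) + rnorm(length(zt), 0, 1)
  r1 <- ejtk(s, zt, n_perm = 199, seed = 6)
  r2 <- ejtk(exp(2 * s), zt, n_perm = 199, seed = 6)
  expect_equal(r1$empirical_p, r2$empirical_p)
  expect_equal(r1$tau, r2$tau, tolerance = 1e-12)
})

test_that("detection power rises with the amplitude/noise ratio", {
  zt <- rep(seq(0, 42, by = 6), each = 3)
  set.seed(26)
  power <- sapply(c(0.3, 1, 2), function(amp)
    mean(replicate(40, {
      s <- amp * cos(2 * pi * zt / 24) + rnorm(length(zt))
      ejtk(s, zt, n_perm = 199)$empirical_p < 0.05
    })))
  expect_true(all(diff(power) >= 0))
})

test_that("rhythm_scan counts significant series per group", {
  zt8 <- seq(0, 42, by = 6)
  meta <- data.frame(sample_id = paste0("s", 1:48),
                     subject_id = rep(paste0("m", 1:3), 16),
                     group = rep(c("FA", "FR"), each = 24),
                     zt_hours = c(rep(zt8, each = 3), rep(zt8, each = 3)))
  set.seed(27)
  flat <- matrix(rnorm(48 * 3), 48, 3,
                 dimnames = list(meta$sample_id, paste0("CAG", 1:3)))
  # a strong oscillation only in the FR half of CAG1
  flat[meta$group == "FR", "CAG1"] <-
    3 * cos(2 * pi * (meta$zt_hours[meta$group == "FR"] - 12) / 24) +
    rnorm(24, 0, 0.3)
  sc <- rhythm_scan(flat, meta, group = "group", n_perm = 499, seed = 3)
  expect_equal(nrow(sc$results), 6)
  expect_true(sc$results$empirical_p[sc$results$group == "FR" &
                                       sc$results$series == "CAG1"] < 0.05)
  expect_gte(sc$n_significant[["FR"]], 1)
})

test_that("strong community oscillation shows up on a leading PCoA axis", {
  set.seed(28)
  cfg <- sim_config(n_subjects = 8, n_features = 40, n_blocks = 4,
                    features_per_block = 10, within_block_corr = 0.6,
                    sparsity_target = NULL, depth = 8000,
                    timecourse_replicates = 3,
                    rhythmic_blocks = data.frame(block = paste0("B", 1:2),
                                                 amplitude = 2, phase = 14))
  tc <- simulate_timecourse(cfg, seed = 5)
  ord <- pcoa(bray_curtis(tc$table))
  pcs <- ord$coordinates[, 1:2]
  sc <- rhythm_scan(pcs, tc$metadata, n_perm = 499, seed = 9)
  expect_true(any(sc$results$empirical_p < 0.05))
})
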