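# small fixtures built in code

tiny_table <- function(values, samples = NULL, features = NULL) {
  m <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(m)))
  if (is.null(features)) features <- paste0("F", seq_len(ncol(m)))
  dimnames(m) <- list(samples, features)
  storage.mode(m) <- "double"
  m
}

tiny_meta <- function(table, subjects = rownames(table)) {
  data.frame(sample_id = rownames(table),
             subject_id = subjects,
             zt_hours = 1,
             stringsAsFactors = FALSE)
}

# paired design: n_subj subjects x 2 samples with feature matrix supplied
paired_meta <- function(n_subj) {
  data.frame(sample_id = paste0("S", seq_len(2 * n_subj)),
             subject_id = rep(paste0("M", seq_len(n_subj)), each = 2),
             stringsAsFactors = FALSE)
}

# symmetric distance matrix with planted blocks (within ~ [0, wmax],
# between ~ [bmin, 2])
block_distance <- function(block_sizes, wmax = 0.4, bmin = 1.4) {
  n <- sum(block_sizes)
  g <- rep(seq_along(block_sizes), block_sizes)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- if (g[i] == g[j]) runif(1, 0, wmax) else
      runif(1, bmin, 2)
  }
  dimnames(m) <- list(paste0("f", seq_len(n)), paste0("f", seq_len(n)))
  attr(m, "blocks") <- g
  m
}

# symmetric matrix with iid U(0, 2) off-diagonal entries
iid_distance <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0, 2)
  m <- m + t(m)
  dimnames(m) <- list(paste0("f", seq_len(n)), paste0("f", seq_len(n)))
  m
}

# the guild-recovery simulation settings used across tests: 60 samples
# (30 subjects x 2), planted blocks, library size 20000
recovery_cfg <- function(n_features, n_blocks, features_per_block, corr) {
  sim_config(n_subjects = 30, n_features = n_features, n_blocks = n_blocks,
             features_per_block = features_per_block,
             within_block_corr = corr, sparsity_target = NULL,
             depth = 20000, block_effects = NULL)
}

recover_cags <- function(cfg, seed, n_perm = 1199, alpha = 0.001) {
  sim <- simulate_community(cfg, seed = seed)
  prev <- prevalence_filter(sim$table, 0.25)
  rc <- rclr(prev)
  corr <- suppressMessages(correlation_matrix(rc, sim$metadata))
  d <- corr_to_distance(corr)
  tr <- ward_tree(d)
  ca <- split_cags(tr, d, alpha = alpha, n_perm = n_perm, seed = seed,
                   table = prev, data = rc, meta = sim$metadata)
  truth <- sim$truth$block[colnames(prev)]
  ok <- !is.na(truth)
  list(assignment = ca$assignment, truth = truth,
       ari = ari(ca$assignment[ok], truth[ok]),
       n_cags = length(unique(ca$assignment)), sim = sim, cags = ca)
}
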