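#' Simulation configuration
#'
#' Builds the parameter list driving the synthetic community generator.
#' Defaults mirror the scale of a four-arm diet x feeding-regime mouse
#' study: 4 groups (NFD/HFD crossed with ad libitum/TRF) x 15 subjects,
#' each sampled at baseline and end of study; ~1100 ASVs of which 34
#' planted co-abundance blocks of 8 ASVs form the prevalent core and the
#' remainder are rare background; ~80% sparsity; library size 25000 (so
#' rarefaction to 18000 is non-trivial); 40% of ASVs unclassifiable at
#' genus level; a 6-h/48-h time-course design with 4 replicates per
#' timepoint.
#'
#' Abundances follow a log-normal latent model: feature log-abundance =
#' base + sigma_bio * (sqrt(w) z_block + sqrt(1-w) eps) + subject-block
#' intercept + group log-fold effect, with `w = within_block_corr` the
#' shared-factor loading, then multinomial sampling at `depth` reads per
#' sample.  Group effects apply at the final timepoint only (treatment
#' effects develop over the study).
#'
#' @param ... overrides of any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_subjects = 60,
    samples_per_subject = 2,
    n_features = 1100,
    n_blocks = 34,
    features_per_block = 8,
    within_block_corr = 0.7,
    sigma_bio = 1,
    subject_sd = 0.5,
    base_mean_block = 1.5, base_sd_block = 1,
    base_mean_bg = -2, base_sd_bg = 1.5,
    block_effects = data.frame(
      block = c("B1", "B7", "B16", "B23", "B27", "B5", "B12"),
      group = "HFD_TRF",
      lfc = c(-1.5, -1.5, 1.5, 1.5, 1.5, 1, -1),
      stringsAsFactors = FALSE),
    unclassifiable_fraction = 0.4,
    sparsity_target = 0.8,
    depth = 25000,
    rhythmic_blocks = data.frame(block = paste0("B", 1:20),
                                 amplitude = 1, phase = 14,
                                 stringsAsFactors = FALSE),
    timecourse_timepoints = seq(0, 42, by = 6),
    timecourse_replicates = 4,
    phenotype_model = NULL,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ", paste(bad, collapse = ", "))
  # whole-field replacement (modifyList would merge into data.frame fields)
  for (nm in names(over)) cfg[nm] <- list(over[[nm]])
  if (is.null(cfg$phenotype_model) && !("phenotype_model" %in% names(over))) {
    # default phenotypes tie glucose outcomes to planted blocks, restricted
    # to blocks that exist at the configured n_blocks
    avail <- function(beta) {
      bl <- paste0("B", seq_len(cfg$n_blocks))
      beta[names(beta) %in% bl]
    }
    g <- avail(c(B16 = -300, B23 = -300, B1 = 300))
    a <- avail(c(B16 = -60000, B27 = -60000, B7 = 60000))
    if (length(g) == 0) g <- c(B1 = 300)
    if (length(a) == 0) a <- c(B1 = 60000)
    cfg$phenotype_model <- list(
      fasting_glucose = list(intercept = 150, noise_sd = 6, beta = g),
      auc_ogtt = list(intercept = 25000, noise_sd = 1200, beta = a))
  }
  with(cfg, {
    stopifnot(within_block_corr >= 0, within_block_corr <= 1,
              unclassifiable_fraction >= 0, unclassifiable_fraction <= 1,
              n_blocks * features_per_block <= n_features,
              depth >= 1)
  })
  if (!is.null(cfg$sparsity_target) &&
      (cfg$sparsity_target < 0 || cfg$sparsity_target > 1))
    stop("sparsity_target must be in [0, 1] or NULL")
  structure(cfg, class = "sim_config")
}

# multinomial counts from a log-mean matrix, with optional uniform cell
# dropout (applied to the sampling probabilities, so per-sample totals
# stay exactly at depth) to reach a sparsity target
.sim_counts <- function(logmu, depth, sparsity_target) {
  draw <- function(lm) {
    pr <- exp(lm - apply(lm, 1, max))
    pr <- pr / rowSums(pr)
    out <- t(apply(pr, 1, function(p) rmultinom(1, depth, p)))
    storage.mode(out) <- "double"
    out
  }
  counts <- draw(logmu)
  if (is.null(sparsity_target)) return(counts)
  s0 <- sparsity(counts) / 100
  if (s0 > sparsity_target + 0.05)
    stop(sprintf("infeasible sparsity target %.2f: sampling alone yields %.2f",
                 sparsity_target, s0))
  if (s0 < sparsity_target) {
    q <- (sparsity_target - s0) / (1 - s0)
    mask <- matrix(runif(length(logmu)) < q, nrow(logmu))
    # never silence a whole sample
    keep1 <- cbind(seq_len(nrow(logmu)), apply(logmu, 1, which.max))
    mask[keep1] <- FALSE
    lm2 <- logmu
    lm2[mask] <- -Inf
    counts <- draw(lm2)
  }
  counts
}

#' Simulate a cross-sectional community with planted guilds
#'
#' Generates counts, metadata and taxonomy according to a `sim_config`,
#' together with the ground truth (feature -> block map, planted effects,
#' unclassifiable set) that downstream recovery tests compare against.
#' Unclassifiable features are picked by systematic sampling along the
#' expected-abundance ranking, so the unclassifiable read share tracks
#' `unclassifiable_fraction` closely as well as the feature share.
#'
#' @param cfg a [sim_config()].
#' @param seed seed (default `cfg$seed`); identical config + seed gives
#'   identical output.
#' @return list with `table` (counts, samples x features, rows summing to
#'   `depth`), `metadata`, `taxonomy` and `truth`.
#' @export
simulate_community <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  nf <- cfg$n_features; nb <- cfg$n_blocks; fpb <- cfg$features_per_block
  feats <- sprintf("ASV%04d", seq_len(nf))
  block <- rep(NA_character_, nf)
  nblocked <- nb * fpb
  block[seq_len(nblocked)] <- rep(paste0("B", seq_len(nb)), each = fpb)
  base <- c(rnorm(nblocked, cfg$base_mean_block, cfg$base_sd_block),
            rnorm(nf - nblocked, cfg$base_mean_bg, cfg$base_sd_bg))

  groups <- c("NFD_AL", "NFD_TRF", "HFD_AL", "HFD_TRF")
  subj <- data.frame(
    subject_id = sprintf("M%03d", seq_len(cfg$n_subjects)),
    group = rep(groups, length.out = cfg$n_subjects),
    stringsAsFactors = FALSE)
  subj$diet <- ifelse(grepl("^HFD", subj$group), "HFD", "NFD")
  subj$regime <- ifelse(grepl("TRF$", subj$group), "TRF", "ad_libitum")
  subj$cage <- paste0("C", (seq_len(cfg$n_subjects) - 1) %/% 3 + 1)

  tp_labels <- if (cfg$samples_per_subject == 2) c("baseline", "week12") else
    paste0("t", seq_len(cfg$samples_per_subject))
  meta <- do.call(rbind, lapply(seq_len(cfg$samples_per_subject), function(t)
    data.frame(sample_id = paste0(subj$subject_id, "_", tp_labels[t]),
               subject_id = subj$subject_id, cage = subj$cage,
               diet = subj$diet, regime = subj$regime, group = subj$group,
               timepoint = tp_labels[t], zt_hours = 1,
               stringsAsFactors = FALSE)))
  ns <- nrow(meta)

  z <- matrix(rnorm(ns * nb), ns, nb)
  u <- matrix(rnorm(cfg$n_subjects * nb, 0, cfg$subject_sd),
              cfg$n_subjects, nb, dimnames = list(subj$subject_id, NULL))
  eps <- matrix(rnorm(ns * nf), ns, nf)
  w <- cfg$within_block_corr
  logmu <- matrix(rep(base, each = ns), ns, nf)
  bi <- match(block, paste0("B", seq_len(nb)))   # block index per feature
  for (j in seq_len(nf)) {
    if (!is.na(bi[j])) {
      logmu[, j] <- logmu[, j] +
        cfg$sigma_bio * (sqrt(w) * z[, bi[j]] + sqrt(1 - w) * eps[, j]) +
        u[meta$subject_id, bi[j]]
    } else {
      logmu[, j] <- logmu[, j] + cfg$sigma_bio * eps[, j]
    }
  }
  if (!is.null(cfg$block_effects) && nrow(cfg$block_effects) > 0) {
    final_tp <- tp_labels[length(tp_labels)]
    for (k in seq_len(nrow(cfg$block_effects))) {
      be <- cfg$block_effects[k, ]
      rows <- meta$group == be$group & meta$timepoint == final_tp
      cols <- which(block == be$block)
      if (!any(rows) || length(cols) == 0) next
      logmu[rows, cols] <- logmu[rows, cols] + be$lfc
    }
  }
  counts <- .sim_counts(logmu, cfg$depth, cfg$sparsity_target)
  dimnames(counts) <- list(meta$sample_id, feats)

  # taxonomy: systematic pick along the abundance ranking keeps the
  # unclassifiable read share close to the feature share
  n_uncls <- round(cfg$unclassifiable_fraction * nf)
  uncls <- character(0)
  if (n_uncls > 0) {
    ord <- order(base, decreasing = TRUE)
    step <- nf / n_uncls
    pos <- ceiling(seq(runif(1, 0, step), by = step, length.out = n_uncls))
    uncls <- feats[ord[pmin(pos, nf)]]
  }
  cls <- setdiff(feats, uncls)
  n_gen <- max(3, round(length(cls) / 5))
  gid <- sample(n_gen, length(cls), replace = TRUE)
  fam <- (gid - 1) %/% 3 + 1
  lineage <- setNames(rep(NA_character_, nf), feats)
  lineage[cls] <- sprintf(
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Oscillospirales; f__Fam%03d; g__Genus%03d",
    fam, gid)
  placeholders <- c(
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Oscillospirales; f__Lachnospiraceae; g__",
    "d__Bacteria; p__Firmicutes; c__Clostridia; o__Oscillospirales; f__Lachnospiraceae; g__uncultured",
    "d__Bacteria; p__Firmicutes; c__Clostridia",
    "d__Bacteria; p__Bacteroidota; c__Bacteroidia; o__Bacteroidales; f__Muribaculaceae; g__unclassified")
  lineage[uncls] <- sample(placeholders, length(uncls), replace = TRUE)
  tax <- parse_taxonomy(feats, unname(lineage[feats]))

  truth <- list(block = setNames(block, feats),
                block_effects = cfg$block_effects,
                unclassifiable = uncls,
                rhythmic_blocks = NULL,
                config = cfg, seed = seed)
  list(table = counts, metadata = meta, taxonomy = tax, truth = truth)
}

#' Simulate a diurnal time course
#'
#' One experimental group's 6-h/48-h time-course: `timecourse_replicates`
#' subjects each sampled at every timepoint.  Blocks listed in `rhythmic`
#' get a cosine term `amplitude * cos(2*pi*(zt - phase)/24)` added to
#' their shared latent mean; with `sigma_bio = 1` the amplitude is the
#' amplitude/noise ratio on the log scale.
#'
#' @param cfg a [sim_config()]; `rhythmic_blocks` provides the default
#'   rhythm set.
#' @param seed seed (default `cfg$seed`).
#' @param rhythmic data.frame(block, amplitude, phase) or `NULL` for a
#'   flat (null) community.
#' @param group_name label written into the metadata `group` column.
#' @return list with `table`, `metadata` (including `zt_hours`) and
#'   `truth`.
#' @export
simulate_timecourse <- function(cfg, seed = cfg$seed,
                                rhythmic = cfg$rhythmic_blocks,
                                group_name = "HFD_TRF") {
  if (!is.null(rhythmic) && any(rhythmic$amplitude < 0))
    stop("rhythm amplitude cannot be negative")
  set.seed(seed)
  nf <- cfg$n_features; nb <- cfg$n_blocks; fpb <- cfg$features_per_block
  feats <- sprintf("ASV%04d", seq_len(nf))
  block <- rep(NA_character_, nf)
  nblocked <- nb * fpb
  block[seq_len(nblocked)] <- rep(paste0("B", seq_len(nb)), each = fpb)
  base <- c(rnorm(nblocked, cfg$base_mean_block, cfg$base_sd_block),
            rnorm(nf - nblocked, cfg$base_mean_bg, cfg$base_sd_bg))
  tps <- cfg$timecourse_timepoints
  reps <- cfg$timecourse_replicates
  meta <- expand.grid(rep = seq_len(reps), zt_hours = tps)
  meta <- data.frame(
    sample_id = sprintf("%s_ZT%02d_r%d", group_name, meta$zt_hours, meta$rep),
    subject_id = sprintf("%s_m%02d", group_name, meta$rep),
    group = group_name,
    timepoint = sprintf("ZT%02d", meta$zt_hours),
    zt_hours = meta$zt_hours, stringsAsFactors = FALSE)
  ns <- nrow(meta)
  z <- matrix(rnorm(ns * nb), ns, nb)
  u <- matrix(rnorm(reps * nb, 0, cfg$subject_sd), reps, nb,
              dimnames = list(unique(meta$subject_id), NULL))
  eps <- matrix(rnorm(ns * nf), ns, nf)
  w <- cfg$within_block_corr
  rhy_amp <- setNames(numeric(nb), paste0("B", seq_len(nb)))
  rhy_phase <- setNames(numeric(nb), paste0("B", seq_len(nb)))
  if (!is.null(rhythmic) && nrow(rhythmic) > 0) {
    if (!all(rhythmic$block %in% names(rhy_amp)))
      stop("rhythmic block outside the configured block set")
    rhy_amp[rhythmic$block] <- rhythmic$amplitude
    rhy_phase[rhythmic$block] <- rhythmic$phase
  }
  cosmod <- vapply(seq_len(nb), function(b)
    rhy_amp[b] * cos(2 * pi * (meta$zt_hours - rhy_phase[b]) / 24),
    numeric(ns))
  bi <- match(block, paste0("B", seq_len(nb)))
  logmu <- matrix(rep(base, each = ns), ns, nf)
  for (j in seq_len(nf)) {
    if (!is.na(bi[j])) {
      logmu[, j] <- logmu[, j] + cosmod[, bi[j]] +
        cfg$sigma_bio * (sqrt(w) * z[, bi[j]] + sqrt(1 - w) * eps[, j]) +
        u[meta$subject_id, bi[j]]
    } else {
      logmu[, j] <- logmu[, j] + cfg$sigma_bio * eps[, j]
    }
  }
  counts <- .sim_counts(logmu, cfg$depth, cfg$sparsity_target)
  dimnames(counts) <- list(meta$sample_id, feats)
  truth <- list(block = setNames(block, feats),
                rhythmic_blocks = rhythmic, config = cfg, seed = seed)
  list(table = counts, metadata = meta, truth = truth)
}

#' Simulate metabolic phenotypes from planted blocks
#'
#' Each phenotype is `intercept + sum(beta_b * relative abundance of
#' block b) + Gaussian noise`, with the block relative abundance computed
#' from the supplied count table via the truth's feature -> block map.
#'
#' @param truth the `truth` element of [simulate_community()].
#' @param table count table whose samples receive phenotypes.
#' @param cfg a [sim_config()] supplying `phenotype_model`.
#' @param seed seed (default `cfg$seed + 1`).
#' @return data.frame with sample_id and one column per phenotype.
#' @export
simulate_phenotypes <- function(truth, table, cfg, seed = cfg$seed + 1) {
  set.seed(seed)
  rel <- table / rowSums(table)
  block_rel <- function(b) {
    members <- intersect(names(truth$block)[!is.na(truth$block) &
                                              truth$block == b],
                         colnames(rel))
    if (length(members) == 0) stop("unknown or absent block: ", b)
    rowSums(rel[, members, drop = FALSE])
  }
  out <- data.frame(sample_id = rownames(table), stringsAsFactors = FALSE)
  for (ph in names(cfg$phenotype_model)) {
    m <- cfg$phenotype_model[[ph]]
    y <- rep(m$intercept, nrow(rel))
    for (b in names(m$beta)) y <- y + m$beta[[b]] * block_rel(b)
    out[[ph]] <- y + rnorm(nrow(rel), 0, m$noise_sd)
  }
  out
}

#' Trapezoidal area under a glucose curve
#'
#' @param values glucose readings.
#' @param times measurement times in minutes, strictly increasing, >= 2.
#' @return the trapezoidal integral in units x minutes.
#' @export
trapezoid_auc <- function(values, times) {
  if (length(values) != length(times) || length(times) < 2)
    stop("need >= 2 aligned (value, time) points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (head(values, -1) + values[-1]) / 2)
}
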