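#' Reference waveforms for rhythm detection
#'
#' Cosine reference patterns \eqn{\cos(2\pi (t - \phi)/period)} evaluated
#' at the sampling timepoints, for phases \eqn{\phi} on a grid of step
#' `phase_step` across one period.  References whose rank pattern
#' duplicates an earlier one (the rank test cannot tell them apart) are
#' dropped.
#'
#' @param timepoints sampling times in hours (Zeitgeber time; may exceed
#'   24 over multi-day series); >= 3 distinct values required.
#' @param period oscillation period in hours (default 24).
#' @param phase_step phase grid step in hours; default the sampling
#'   interval (smallest gap between distinct timepoints modulo the
#'   period).
#' @return timepoints x references matrix with attribute `phases`.
#' @export
reference_waveforms <- function(timepoints, period = 24, phase_step = NULL) {
  if (period <= 0) stop("period must be positive")
  if (length(unique(timepoints)) < 3)
    stop("need at least 3 distinct timepoints")
  if (is.null(phase_step)) {
    tp <- sort(unique(timepoints %% period))
    phase_step <- min(diff(tp))
  }
  phases <- seq(0, period - phase_step, by = phase_step)
  refs <- vapply(phases, function(ph)
    cos(2 * pi * (timepoints - ph) / period), numeric(length(timepoints)))
  refs <- matrix(refs, nrow = length(timepoints))
  keep <- !duplicated(apply(refs, 2, function(v) paste(rank(v), collapse = ",")))
  refs <- refs[, keep, drop = FALSE]
  attr(refs, "phases") <- phases[keep]
  refs
}

#' Rank concordance between a series and a reference waveform
#'
#' Kendall's tau-b between the observed values and the reference values;
#' replicates within a timepoint share the reference value, and the tie
#' correction of tau-b accounts for those shared levels.
#'
#' @param series observed values.
#' @param reference reference waveform values, aligned with `series`.
#' @return tau in [-1, 1]; a constant series returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
jtk_statistic <- function(series, reference) {
  if (length(series) != length(reference))
    stop("series and reference must have equal length")
  if (length(unique(series)) < 2)
    return(structure(0, degenerate = TRUE))
  .kendall_tau_b_cpp(as.numeric(series), as.numeric(reference))
}

#' Empirical JTK_CYCLE rhythm test at a set period
#'
#' The observed statistic is the maximum tau-b over the phased cosine
#' reference family; significance comes from permuting the observed
#' values across all time-replicate slots:
#' `p = (1 + #[max-tau* >= max-tau]) / (1 + n_perm)`.  Being rank-based,
#' the p-value is invariant to any strictly monotone transform of the
#' series.
#'
#' @param series observed values (replicates allowed).
#' @param timepoints zt hours aligned with `series`.
#' @param period set period in hours (default 24).
#' @param phase_step phase grid step (default: sampling interval).
#' @param n_perm permutations (default 999, >= 199 recommended).
#' @param seed optional seed.
#' @return list with `tau`, `best_phase` (hours), `empirical_p`, `period`,
#'   `n_perm`.
#' @export
ejtk <- function(series, timepoints, period = 24, phase_step = NULL,
                 n_perm = 999, seed = NULL) {
  if (length(series) != length(timepoints))
    stop("series and timepoints must have equal length")
  if (!is.null(seed)) set.seed(seed)
  refs <- reference_waveforms(timepoints, period, phase_step)
  if (length(unique(series)) < 2)
    return(list(tau = 0, best_phase = NA_real_, empirical_p = 1,
                period = period, n_perm = n_perm))
  obs <- .max_tau_cpp(matrix(as.numeric(series)), refs)
  perms <- vapply(seq_len(n_perm), function(i) sample(as.numeric(series)),
                  numeric(length(series)))
  pt <- .max_tau_cpp(perms, refs)$tau
  p <- (1 + sum(pt >= obs$tau[1] - 1e-12)) / (1 + n_perm)
  list(tau = obs$tau[1], best_phase = attr(refs, "phases")[obs$which[1]],
       empirical_p = p, period = period, n_perm = n_perm)
}

#' Scan many series for diurnal rhythmicity
#'
#' Applies [ejtk()] to every column of a feature table (CAG, ASV or
#' principal-coordinate series), per group when a grouping is supplied —
#' each group's scan uses only that group's samples.
#'
#' @param table samples x series matrix (rows matched to `meta` by
#'   sample_id).
#' @param meta metadata with `sample_id` and `zt_hours` (and the grouping
#'   column, if used).
#' @param group optional name of a metadata column splitting samples into
#'   groups scanned separately.
#' @param period,phase_step,n_perm,seed passed to [ejtk()].
#' @param alpha significance level for the summary counts (default 0.05).
#' @return list with `results` (data.frame group, series, tau, best_phase,
#'   empirical_p) and `n_significant` (per-group count at `p < alpha`).
#' @export
rhythm_scan <- function(table, meta, group = NULL, period = 24,
                        phase_step = NULL, n_perm = 999, seed = NULL,
                        alpha = 0.05) {
  idx <- match(rownames(table), meta$sample_id)
  if (anyNA(idx)) stop("every sample needs a metadata row with zt_hours")
  zt <- meta$zt_hours[idx]
  grp <- if (is.null(group)) rep("all", nrow(table)) else
    as.character(meta[[group]][idx])
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in unique(grp)) {
    sel <- grp == g
    for (s in colnames(table)) {
      r <- ejtk(table[sel, s], zt[sel], period = period,
                phase_step = phase_step, n_perm = n_perm)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, series = s, tau = r$tau, best_phase = r$best_phase,
        empirical_p = r$empirical_p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  nsig <- tapply(res$empirical_p < alpha, res$group, sum)
  list(results = res, n_significant = nsig, alpha = alpha, period = period)
}
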