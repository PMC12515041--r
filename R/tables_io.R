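#' Validate a feature table
#'
#' A feature table is a numeric matrix with samples as rows and features
#' (ASVs, genera or CAGs) as columns, sample ids as rownames and feature
#' ids as colnames.  Entries are non-negative counts or relative
#' abundances.
#'
#' @param table matrix to validate.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("feature table must be a numeric matrix (samples x features)")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("feature table must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(rownames(table)))
    stop("duplicated sample ids in feature table")
  if (anyDuplicated(colnames(table)))
    stop("duplicated feature ids in feature table")
  if (anyNA(table) || any(table < 0))
    stop("feature table entries must be non-negative and non-missing")
  invisible(table)
}

#' Read / write a feature table
#'
#' Tab-separated, UTF-8, samples as rows; the first header cell is
#' `sample-id` followed by feature ids (the layout of a QIIME2-exported
#' table).  `write_feature_table` then `read_feature_table` round-trips the
#' values and orderings exactly.
#'
#' @param path file path.
#' @return a validated feature table matrix.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs a sample-id column and >= 1 feature")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_feature_table(m)
  m
}

#' @rdname read_feature_table
#' @param table feature table matrix.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  df <- data.frame(`sample-id` = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample-id`, `subject-id`, `cage`, `diet`, `regime`,
#' `timepoint`, `zt_hours`.  `zt_hours` is hours since lights-on (ZT0) and
#' may exceed 24 over multi-day time courses.
#'
#' @param path file path.
#' @return data.frame with columns sample_id, subject_id, cage, diet,
#'   regime, timepoint, zt_hours.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- gsub("-", "_", names(df))
  req <- c("sample_id", "subject_id")
  if (!all(req %in% names(df)))
    stop("metadata must contain sample-id and subject-id columns")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in metadata")
  if ("zt_hours" %in% names(df)) {
    df$zt_hours <- as.numeric(df$zt_hours)
    if (any(df$zt_hours < 0, na.rm = TRUE)) stop("zt_hours must be >= 0")
  }
  df
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- meta
  names(out) <- sub("^sample_id$", "sample-id",
                    sub("^subject_id$", "subject-id", names(out)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric draw) so that every retained sample sums exactly to
#' `depth`.  Samples with fewer than `depth` total reads are dropped with a
#' warning.
#'
#' @param table integer count feature table.
#' @param depth target reads per sample (default 18000, the depth used for
#'   16S V3-V4 libraries in the workflow this package mirrors).
#' @param seed optional integer seed for the draw.
#' @return rarefied feature table.
#' @export
rarefy <- function(table, depth = 18000, seed = NULL) {
  validate_feature_table(table)
  if (any(table != round(table))) stop("rarefy requires integer counts")
  if (length(depth) != 1 || depth < 1) stop("depth must be a single integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) with fewer than %d reads",
                    sum(!keep), depth))
  if (!any(keep)) stop("no sample reaches the rarefaction depth")
  sub <- table[keep, , drop = FALSE]
  p <- ncol(sub)
  out <- t(apply(sub, 1, function(row) {
    if (sum(row) == depth) return(row)
    pool <- rep.int(seq_len(p), row)
    tabulate(pool[sample.int(length(pool), depth)], nbins = p)
  }))
  dimnames(out) <- dimnames(sub)
  out
}

#' Filter features by prevalence
#'
#' Keeps features whose fraction of non-zero samples exceeds `min_prev`.
#' The comparison is strict (`>`) by default, reading "present in over 25%
#' of the samples" literally; set `strict = FALSE` for `>=`.
#'
#' @param table feature table.
#' @param min_prev prevalence fraction in [0, 1).
#' @param strict use strict `>` (default) rather than `>=`.
#' @return filtered feature table, feature order preserved.
#' @export
prevalence_filter <- function(table, min_prev = 0.25, strict = TRUE) {
  validate_feature_table(table)
  if (min_prev < 0 || min_prev >= 1) stop("min_prev must be in [0, 1)")
  prev <- colMeans(table > 0)
  keep <- if (strict) prev > min_prev else prev >= min_prev
  if (!any(keep)) warning("prevalence filter removed every feature")
  table[, keep, drop = FALSE]
}

#' Sparsity of a table
#'
#' Percentage of zero cells.
#'
#' @param table feature table.
#' @return percent of cells equal to zero.
#' @export
sparsity <- function(table) {
  if (length(table) == 0) stop("sparsity of an empty table is undefined")
  100 * sum(table == 0) / length(table)
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Percent of reads retained
#'
#' `100 * reads / total`, rounded half-up to `digits` decimals; `digits =
#' 1` reproduces one-decimal printed cells.
#'
#' @param reads reads retained at a stage.
#' @param total total reads of the reference (rarefied ASV) table.
#' @param digits decimal places (default 2).
#' @return percentage.
#' @export
pct_reads <- function(reads, total, digits = 2) {
  if (total <= 0) stop("total reads must be positive")
  round_half_up(100 * reads / total, digits)
}

#' Four-level data-reduction ledger
#'
#' Summarises how much of the original dataset survives each level of a
#' data-reduction cascade (level 1: feature selection; level 2: aggregation
#' into composite variables; level 3: treatment-responding variables;
#' level 4: health-relevant variables), for the guild-based and genus-based
#' methods side by side.  All percentages share one denominator: the grand
#' read sum of the rarefied ASV table.
#'
#' @param stages list of stages; each stage is a list with elements
#'   `level` (1-4), `method` ("guild" or "genus") and either `table` (a
#'   feature table whose grand sum is the stage's retained reads, since
#'   aggregation conserves member reads) or `reads` plus optional
#'   `n_variables` and `sparsity_pct` for stages known only by their
#'   printed counts.
#' @param total_reads the shared denominator.
#' @param digits decimal places for the percent column (default 2).
#' @return data.frame with columns level, method, n_variables,
#'   reads_retained, pct_reads, total_reads, sparsity_pct.
#' @export
reduction_ledger <- function(stages, total_reads, digits = 2) {
  if (length(total_reads) != 1 || total_reads <= 0)
    stop("total_reads must be a single positive number")
  rows <- lapply(stages, function(st) {
    if (is.null(st$level) || !st$level %in% 1:4)
      stop("each stage needs a level in 1..4")
    if (is.null(st$method) || !st$method %in% c("guild", "genus"))
      stop("each stage needs method 'guild' or 'genus'")
    if (!is.null(st$table)) {
      validate_feature_table(st$table)
      reads <- sum(st$table)
      nvar <- ncol(st$table)
      sp <- sparsity(st$table)
    } else {
      reads <- st$reads
      nvar <- if (is.null(st$n_variables)) NA_integer_ else st$n_variables
      sp <- if (is.null(st$sparsity_pct)) NA_real_ else st$sparsity_pct
    }
    if (reads > total_reads + 1e-6)
      stop("stage retains more reads than the total; wrong denominator?")
    data.frame(level = st$level, method = st$method, n_variables = nvar,
               reads_retained = reads,
               pct_reads = pct_reads(reads, total_reads, digits),
               total_reads = total_reads,
               sparsity_pct = round_half_up(sp, digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname reduction_ledger
#' @param ledger a ledger data.frame.
#' @param path output TSV path.
#' @export
write_ledger <- function(ledger, path) {
  write.table(ledger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
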