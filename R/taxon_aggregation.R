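#' Parse a taxonomy table
#'
#' Reads a QIIME2-export style taxonomy TSV ("Feature ID", "Taxon",
#' optional "Confidence" ignored) with semicolon-delimited SILVA-style rank
#' strings (`d__; p__; c__; o__; f__; g__; ...`) and flags whether each
#' feature is classifiable at genus level.  A feature is unclassifiable
#' when its genus rank is absent (lineage shorter than six ranks), empty
#' (`g__` or blank), or a placeholder token (`uncultured...`,
#' `unclassified...` by default).
#'
#' @param path taxonomy TSV path.
#' @param placeholder_prefixes genus tokens (after stripping `g__`)
#'   treated as unclassifiable, matched as prefixes, case-insensitive.
#' @return data.frame with feature_id, taxon, genus (full lineage down to
#'   genus, `NA` when unclassifiable) and classifiable_at_genus.
#' @export
read_taxonomy <- function(path,
                          placeholder_prefixes = c("uncultured", "unclassified")) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("feature_id", "taxon")
  parse_taxonomy(df$feature_id, df$taxon, placeholder_prefixes)
}

#' @rdname read_taxonomy
#' @param feature_ids feature identifiers.
#' @param taxa semicolon-delimited lineage strings aligned with
#'   `feature_ids`.
#' @export
parse_taxonomy <- function(feature_ids, taxa,
                           placeholder_prefixes = c("uncultured", "unclassified")) {
  if (anyDuplicated(feature_ids)) stop("duplicated feature ids in taxonomy")
  ranks <- strsplit(taxa, ";", fixed = TRUE)
  genus <- vapply(ranks, function(rk) {
    rk <- trimws(rk)
    if (length(rk) < 6) return(NA_character_)
    g <- sub("^g__", "", rk[6])
    if (!nzchar(g)) return(NA_character_)
    low <- tolower(g)
    for (pp in placeholder_prefixes)
      if (startsWith(low, tolower(pp))) return(NA_character_)
    # genus identity is the lineage down to genus, not the bare name,
    # so homonymous genera in different families stay distinct
    paste(rk[1:6], collapse = ";")
  }, character(1))
  data.frame(feature_id = as.character(feature_ids),
             taxon = as.character(taxa), genus = genus,
             classifiable_at_genus = !is.na(genus),
             stringsAsFactors = FALSE)
}

#' Aggregate ASVs to genus level
#'
#' Sums classifiable features sharing a genus lineage into one genus
#' column; unclassifiable features are excluded and their read totals
#' reported.  Reads of the genus table plus excluded reads equal the input
#' total exactly.
#'
#' @param table feature table (samples x ASVs).
#' @param tax taxonomy from [read_taxonomy()]/[parse_taxonomy()] covering
#'   every feature of `table`.
#' @return list with `genus_table` (samples x genera), `excluded`
#'   (unclassifiable feature ids), `excluded_reads` and
#'   `excluded_read_fraction`.
#' @export
aggregate_genus <- function(table, tax) {
  validate_feature_table(table)
  idx <- match(colnames(table), tax$feature_id)
  if (anyNA(idx)) stop("taxonomy must cover every feature of the table")
  tax <- tax[idx, ]
  cls <- tax$classifiable_at_genus
  excluded <- colnames(table)[!cls]
  genera <- unique(tax$genus[cls])
  gt <- vapply(genera, function(g)
    rowSums(table[, which(cls & tax$genus == g), drop = FALSE]),
    numeric(nrow(table)))
  gt <- matrix(gt, nrow = nrow(table),
               dimnames = list(rownames(table), genera))
  ex_reads <- sum(table[, excluded, drop = FALSE])
  list(genus_table = gt, excluded = excluded, excluded_reads = ex_reads,
       excluded_read_fraction = ex_reads / sum(table))
}

#' @rdname aggregate_genus
#' @param genus_table a genus-level feature table.
#' @param min_prev prevalence fraction; strict `>` rule as in
#'   [prevalence_filter()].
#' @param strict use strict `>` (default).
#' @export
genus_prevalence_filter <- function(genus_table, min_prev = 0.25, strict = TRUE) {
  prevalence_filter(genus_table, min_prev = min_prev, strict = strict)
}

#' Track health-relevant ASVs across the two methods
#'
#' Compares the ASV memberships behind the guild-side and genus-side
#' health-relevant variables: shared ASVs, each side's exclusive ASVs, and
#' the read counts / percent of total reads each set carries.
#'
#' @param guild_asvs ASV ids inside the health-relevant CAGs.
#' @param genus_asvs ASV ids inside the health-relevant genera.
#' @param table the full ASV table supplying the read denominator.
#' @return list with `shared`, `guild_only`, `genus_only` (each a list of
#'   ids, reads and pct_reads) and `n_shared`.
#' @export
track_asvs <- function(guild_asvs, genus_asvs, table) {
  total <- sum(table)
  summarise <- function(ids) {
    ids <- intersect(ids, colnames(table))
    reads <- sum(table[, ids, drop = FALSE])
    list(ids = ids, reads = reads, pct_reads = 100 * reads / total)
  }
  shared <- intersect(guild_asvs, genus_asvs)
  list(shared = summarise(shared),
       guild_only = summarise(setdiff(guild_asvs, genus_asvs)),
       genus_only = summarise(setdiff(genus_asvs, guild_asvs)),
       n_shared = length(shared))
}
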