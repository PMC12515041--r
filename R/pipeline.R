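#' Full guild-vs-genus study driver
#'
#' Runs the complete analysis flow on one dataset: rarefaction,
#' prevalence filtering, rCLR, repeated-observations correlation, Ward
#' tree + PERMANOVA clade splitting into CAGs, CAG abundance assembly,
#' the genus-level comparator, the four-level data-reduction ledger,
#' Bray-Curtis ordinations with Procrustes/PROTEST concordance and the
#' information-loss score, and (when labels and phenotypes are available)
#' Boruta marker selection with ROC validation and the Spearman phenotype
#' screen on both the CAG and genus side.  Any stage failure aborts with
#' the stage name prefixed to the error.
#'
#' @param table ASV count table (matrix) or path to its TSV.
#' @param metadata sample metadata (data.frame) or path.
#' @param taxonomy taxonomy (data.frame from [parse_taxonomy()]) or path;
#'   `NULL` skips the genus comparator (an error if `genus = TRUE`).
#' @param phenotypes phenotype data.frame (`sample_id` + numeric columns)
#'   or path, or `NULL` to skip the phenotype screen.
#' @param out_dir optional directory; when given, every stage product is
#'   written there as TSV together with a run log of seeds, thresholds
#'   and input hashes.
#' @param depth rarefaction depth (default 18000).
#' @param prevalence prevalence cutoff (default 0.25, strict).
#' @param alpha per-split PERMANOVA cutoff (default 0.001).
#' @param n_perm PERMANOVA permutations (default 9999).
#' @param n_perm_protest PROTEST permutations (default 999).
#' @param marker_groups two values of `metadata$group` to contrast in the
#'   marker stage (default the HFD ad-libitum vs TRF arms); `NULL` skips
#'   markers.
#' @param marker_timepoint metadata timepoint used for the marker
#'   contrast (default the last).
#' @param genus run the genus comparator (default `TRUE` when taxonomy is
#'   supplied).
#' @param seed master seed for every stochastic stage.
#' @return list bundle with the rarefied and filtered tables, correlation
#'   and distance matrices, tree, `cags`, `cag_table`, genus results,
#'   `ledger`, ordinations, `procrustes` + `information_loss`, and marker
#'   results per method.
#' @export
run_full <- function(table, metadata, taxonomy = NULL, phenotypes = NULL,
                     out_dir = NULL, depth = 18000, prevalence = 0.25,
                     alpha = 0.001, n_perm = 9999, n_perm_protest = 999,
                     marker_groups = c("HFD_AL", "HFD_TRF"),
                     marker_timepoint = NULL,
                     genus = !is.null(taxonomy), seed = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(table)) table <- read_feature_table(table)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(phenotypes))
    phenotypes <- read.delim(phenotypes, check.names = FALSE)
  if (genus && is.null(taxonomy))
    stop("[genus] genus comparator requested but no taxonomy supplied")

  rar <- stage("rarefy", rarefy(table, depth = depth, seed = seed))
  meta <- metadata[metadata$sample_id %in% rownames(rar), , drop = FALSE]
  total_reads <- sum(rar)
  prev <- stage("prevalence", prevalence_filter(rar, min_prev = prevalence))
  rc <- stage("rclr", rclr(prev))
  corr <- stage("correlation", correlation_matrix(rc, meta))
  dmat <- stage("distance", corr_to_distance(corr))
  tree <- stage("ward", ward_tree(dmat))
  set.seed(seed)
  cags <- stage("split_cags",
                split_cags(tree, dmat, alpha = alpha, n_perm = n_perm,
                           table = prev, data = rc, meta = meta))
  cag_tab <- stage("cag_abundance", cag_abundance(prev, cags))

  genus_res <- NULL
  genus_prev <- NULL
  if (genus) {
    genus_res <- stage("aggregate_genus", aggregate_genus(rar, taxonomy))
    genus_prev <- stage("genus_prevalence",
                        genus_prevalence_filter(genus_res$genus_table,
                                                min_prev = prevalence))
  }

  # ordinations against the full rarefied ASV table
  ord_asv <- stage("ordination", pcoa(bray_curtis(rar)))
  rel_cag <- cag_tab / rowSums(rar)
  ord_cag <- stage("ordination", pcoa(bray_curtis(rel_cag)))
  set.seed(seed + 1)
  pro_cag <- stage("procrustes",
                   procrustes_compare(ord_asv, ord_cag,
                                      n_perm = n_perm_protest))
  pro_genus <- NULL
  loss <- NULL
  if (genus) {
    rel_gen <- genus_prev / rowSums(rar)
    ord_gen <- stage("ordination", pcoa(bray_curtis(rel_gen)))
    set.seed(seed + 2)
    pro_genus <- stage("procrustes",
                       procrustes_compare(ord_asv, ord_gen,
                                          n_perm = n_perm_protest))
    loss <- stage("information_loss",
                  information_loss(pro_genus$m12_squared,
                                   pro_cag$m12_squared))
  }

  # marker discovery on each method's aggregated variables
  markers <- list()
  if (!is.null(marker_groups) && "group" %in% names(meta)) {
    if (is.null(marker_timepoint))
      marker_timepoint <- utils::tail(unique(meta$timepoint), 1)
    run_markers <- function(tab, tag, sd_offset) {
      sel <- meta$group %in% marker_groups &
        meta$timepoint == marker_timepoint
      ids <- meta$sample_id[sel]
      x <- tab[rownames(tab) %in% ids, , drop = FALSE]
      y <- factor(meta$group[match(rownames(x), meta$sample_id)],
                  levels = marker_groups)
      set.seed(seed + sd_offset)
      b <- boruta(x, y)
      conf <- names(b$status)[b$status == "confirmed"]
      auc <- if (length(conf) > 0)
        classifier_auc(x[, conf, drop = FALSE], y) else NULL
      scr <- NULL
      hr <- character(0)
      if (!is.null(phenotypes)) {
        ph <- phenotypes[match(rownames(x), phenotypes$sample_id), ,
                         drop = FALSE]
        num <- ph[, setdiff(names(ph), "sample_id"), drop = FALSE]
        rownames(num) <- rownames(x)
        scr <- spearman_screen(x, num)
        hr <- health_relevant(b, scr)
      }
      list(tag = tag, boruta = b, confirmed = conf, auc = auc,
           screen = scr, health_relevant = hr)
    }
    markers$guild <- stage("markers",
                           run_markers(cag_tab / rowSums(rar), "guild", 10))
    if (genus)
      markers$genus <- stage("markers",
                             run_markers(genus_prev / rowSums(rar),
                                         "genus", 20))
  }

  # four-level reduction ledger (levels 3/4 need marker results)
  ledger_stages <- list(
    list(level = 1, method = "guild", table = prev),
    list(level = 2, method = "guild", table = cag_tab))
  if (genus) {
    cls_tab <- rar[, colnames(rar)[!colnames(rar) %in% genus_res$excluded],
                   drop = FALSE]
    ledger_stages <- c(ledger_stages, list(
      list(level = 1, method = "genus", table = cls_tab),
      list(level = 2, method = "genus", table = genus_prev)))
  }
  add_marker_levels <- function(stages, mk, tab, method) {
    if (is.null(mk)) return(stages)
    if (length(mk$confirmed) > 0)
      stages <- c(stages, list(list(level = 3, method = method,
                                    table = tab[, mk$confirmed, drop = FALSE])))
    if (length(mk$health_relevant) > 0)
      stages <- c(stages, list(list(level = 4, method = method,
                                    table = tab[, mk$health_relevant,
                                                drop = FALSE])))
    stages
  }
  ledger_stages <- add_marker_levels(ledger_stages, markers$guild, cag_tab,
                                     "guild")
  if (genus)
    ledger_stages <- add_marker_levels(ledger_stages, markers$genus,
                                       genus_prev, "genus")
  ledger <- stage("ledger", reduction_ledger(ledger_stages, total_reads))

  bundle <- list(rarefied = rar, prevalent = prev, rclr = rc,
                 correlation = corr, distance = dmat, tree = tree,
                 cags = cags, cag_table = cag_tab, genus = genus_res,
                 genus_prevalent = genus_prev, ledger = ledger,
                 ordination_asv = ord_asv, ordination_cag = ord_cag,
                 procrustes_cag = pro_cag, procrustes_genus = pro_genus,
                 information_loss = loss, markers = markers,
                 params = list(depth = depth, prevalence = prevalence,
                               alpha = alpha, n_perm = n_perm,
                               n_perm_protest = n_perm_protest,
                               seed = seed))
  if (!is.null(out_dir)) stage("write", write_bundle(bundle, out_dir))
  bundle
}

#' @rdname run_full
#' @param bundle a `run_full()` result.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_feature_table(bundle$rarefied, fp("rarefied_asv_table.tsv"))
  write_feature_table(bundle$prevalent, fp("prevalent_asv_table.tsv"))
  write_correlation_matrix(bundle$correlation, fp("asv_correlation.tsv"))
  write_tree_newick(bundle$tree, fp("ward_tree.nwk"))
  write_cag_assignment(bundle$cags, fp("cag_assignment.tsv"))
  write_feature_table(bundle$cag_table, fp("cag_table.tsv"))
  if (!is.null(bundle$genus_prevalent))
    write_feature_table(bundle$genus_prevalent, fp("genus_table.tsv"))
  write_ledger(bundle$ledger, fp("reduction_ledger.tsv"))
  write_ordination(bundle$ordination_asv, fp("ordination_asv.txt"))
  write_ordination(bundle$ordination_cag, fp("ordination_cag.txt"))
  for (m in bundle$markers) {
    write_boruta(m$boruta, fp(sprintf("boruta_%s.tsv", m$tag)))
    if (!is.null(m$screen))
      write_screen(m$screen, fp(sprintf("screen_%s.tsv", m$tag)))
  }
  files <- list.files(out_dir, full.names = TRUE)
  log <- c(sprintf("guildcraft %s | R %s",
                   as.character(utils::packageVersion("guildcraft")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed=%d depth=%d prevalence=%g alpha=%g n_perm=%d n_perm_protest=%d",
                   bundle$params$seed, bundle$params$depth,
                   bundle$params$prevalence, bundle$params$alpha,
                   bundle$params$n_perm, bundle$params$n_perm_protest),
           sprintf("%s  %s", tools::md5sum(files), basename(files)))
  writeLines(log, fp("run_log.txt"))
  invisible(out_dir)
}
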