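# guildcraft

Guild-based (co-abundance group) analysis of amplicon microbiome data,
with a genus-level comparator, rhythm detection and a ground-truth
synthetic generator.

## The problem

16S surveys resolve a gut community into amplicon sequence variants
(ASVs). The conventional next step — aggregate ASVs into genera — discards
every ASV that cannot be classified at genus level and averages together
ASVs of one genus that may respond to a treatment in opposite directions.
A guild-based analysis instead groups prevalent ASVs into **co-abundance
groups (CAGs)**: sets of ASVs whose abundances covary across samples,
treated as single functional units whose abundance is the sum of their
members. `guildcraft` implements that workflow end to end and the
bookkeeping needed to compare it fairly against the genus route.

## The method

Starting from an ASV count table, sample metadata (subject, group,
timepoint), and optionally a QIIME2-style taxonomy and phenotype table:

1. rarefy to even depth (default 18 000 reads/sample, hypergeometric);
2. keep ASVs present in over 25% of samples;
3. robust CLR transform (zeros treated as missing, no pseudocounts);
4. correlation between ASVs by the repeated-observations (within-subject)
   estimator,
   r = Σᵢⱼ(xᵢⱼ−x̄ᵢ)(yᵢⱼ−ȳᵢ) / √(Σᵢⱼ(xᵢⱼ−x̄ᵢ)² · Σᵢⱼ(yᵢⱼ−ȳᵢ)²),
   pooling subject-centred sums over subjects i and occasions j;
5. Ward clustering of the 1−r distance, then consecutive two-group
   PERMANOVA tests from the top of the tree (cutoff P < .001, selection-aware
   permutation null) to delimit CAGs; CAG abundance = sum of member ASVs;
6. genus comparator (classifiable ASVs summed per genus lineage, excluded
   reads tracked) and a four-level data-reduction ledger (variables, reads
   retained, sparsity at each reduction level for both methods);
7. Bray–Curtis / PCoA ordinations, PERMANOVA group tests (BH-adjusted),
   Procrustes superimposition against the full ASV ordination with the
   **information-loss score** = m₁₂²(genus) / m₁₂²(CAG);
8. marker discovery: Boruta-style shadow-feature random-forest selection,
   repeated-CV ROC/AUC validation, Spearman + BH phenotype screening;
9. diurnal rhythm detection: empirical JTK_CYCLE at a set 24-h period
   (max Kendall tau-b against phased cosine references, permutation
   p-values), per experimental group.

A synthetic-data module (`sim_config`, `simulate_community`,
`simulate_timecourse`, `simulate_phenotypes`) generates study-shaped data
with known planted guilds, group effects, rhythms and phenotype links, so
every stage is testable without any sequencing data.

## Worked example

```r
library(guildcraft)

cfg <- sim_config(n_subjects = 24, n_features = 120, n_blocks = 8,
                  features_per_block = 12, within_block_corr = 0.65,
                  sparsity_target = NULL, depth = 12000,
                  block_effects = data.frame(block = c("B1", "B2", "B3"),
                                             group = "HFD_TRF",
                                             lfc = c(1.5, -1.5, 1.2)))
sim <- simulate_community(cfg, seed = 7)
ph  <- simulate_phenotypes(sim$truth, sim$table, cfg, seed = 8)

res <- run_full(sim$table, sim$metadata, sim$taxonomy, phenotypes = ph,
                depth = 10000, n_perm = 1999, n_perm_protest = 199, seed = 7)

res$cags
#> cag_assignment: 118 features in 13 CAGs (alpha = 0.001)
#>   25 nodes examined: 12 split, 9 kept, 4 untestable

res$ledger[, c("level", "method", "n_variables", "pct_reads", "sparsity_pct")]
#>   level method n_variables pct_reads sparsity_pct
#> 1     1  guild         118    100.00         6.71
#> 2     2  guild          13    100.00         0.48
#> 3     1  genus          72     62.18         7.47
#> 4     2  genus          14     62.18         0.00
#> 5     3  guild           4     49.93         0.00
#> 6     4  guild           3     41.53         0.00
#> 7     3  genus           5     22.79         0.00
#> 8     4  genus           5     22.79         0.00

res$information_loss
#> [1] 1.302693

res$markers$guild$confirmed
#> [1] "CAG1"  "CAG2"  "CAG7"  "CAG10"
res$markers$guild$health_relevant
#> [1] "CAG1"  "CAG2"  "CAG10"
res$markers$guild$auc$auc
#> [1] 1
```

Reading this: all 118 prevalent ASVs form 13 CAGs that keep 100% of the
rarefied reads at near-zero sparsity, while the genus route keeps 62.2% in
14 genera (the planted unclassifiable ASVs are excluded); the
information-loss score of 1.30 means the genus ordination strayed ~30%
further from the full ASV ordination than the CAG ordination did. The
Boruta stage confirms four CAGs as group-discriminating (the three planted
group-shifted blocks are among them), the phenotype screen narrows them to
three health-relevant CAGs, and the repeated-CV classifier on the
confirmed CAGs separates the two HFD arms perfectly.

## Shell usage

A thin wrapper over the package functions lives in
`inst/scripts/guildcraft.R`:

```sh
Rscript inst/scripts/guildcraft.R simulate --out sim_out --seed 1
Rscript inst/scripts/guildcraft.R full --table sim_out/table.tsv \
  --metadata sim_out/metadata.tsv --taxonomy sim_out/taxonomy.tsv \
  --phenotypes sim_out/phenotypes.tsv --out study_out --seed 1
```
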