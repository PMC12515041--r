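---
title: "Guild-based microbiome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild-based microbiome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildcraft)
```

## The problem

Amplicon surveys describe a gut community as counts of thousands of exact
sequence variants (ASVs). Conventional analyses aggregate ASVs into genera
before asking biological questions, which has two costs: ASVs that cannot
be classified at genus level are discarded wholesale, and ASVs of one genus
with opposite ecological behaviour are averaged into a single variable that
may track nothing real. The guild-based alternative groups ASVs by how
their abundances *covary* across samples — a co-abundance group (CAG) is a
set of ASVs that rise and fall together and is treated as one functional
unit whose abundance is the sum of its members. `guildcraft` implements the
full guild workflow, the genus comparator, and the bookkeeping needed to
compare the two fairly.

## The pipeline and its model assumptions

1. **Rarefaction** (`rarefy`). Counts are subsampled without replacement
   (multivariate hypergeometric) to a common depth, by default 18 000
   reads/sample; shallower samples are dropped with a warning. This
   equalises the sampling effort that downstream presence/absence and
   dissimilarity computations are sensitive to.
2. **Prevalence filter** (`prevalence_filter`). Only ASVs present in *over*
   25% of samples (strict `>`; a flag gives `>=`) enter the co-abundance
   analysis: correlations between mostly-absent features are dominated by
   their shared zeros. Prevalence is computed over all samples supplied
   (both sampling occasions pooled); the workflow does not distinguish
   occasions here, and the choice is deliberate — a guild is defined by
   covariation across the whole study.
3. **Robust CLR** (`rclr`). Each count becomes
   `ln(count / geometric mean of the sample's non-zero counts)`; zeros are
   treated as missing rather than pseudocounted, so no imputation
   influences the correlation structure.
4. **Repeated-observations correlation** (`rm_correlation`,
   `correlation_matrix`). Subjects are sampled twice (baseline and end of
   study), so ordinary correlations would mix within-subject covariation
   with stable between-subject differences. The within-subject estimator
   pools subject-centred sums of products:
   \[ r = \frac{\sum_{ij}(x_{ij}-\bar x_i)(y_{ij}-\bar y_i)}
   {\sqrt{\sum_{ij}(x_{ij}-\bar x_i)^2\,\sum_{ij}(y_{ij}-\bar y_i)^2}}. \]
   Missing (zero-count) cells are dropped pairwise; the subject means are
   recomputed on each pair's shared support. Pairs left with fewer than
   two within-subject residual degrees of freedom are undefined and enter
   the distance matrix as r = 0 (neutral distance 1), with a logged count.
5. **Distance, tree, clade splitting** (`corr_to_distance`, `ward_tree`,
   `split_cags`). The `1 - r` distance is clustered with Ward linkage
   (Ward.D2 criterion by default; Ward.D available). The tree is then
   walked from the root: each internal node's two child clades define a
   two-group PERMANOVA pseudo-F on the node's distances, and the split is
   accepted when its permutation p-value falls below 0.001 — otherwise the
   node becomes one CAG. CAG abundance is the sum of member ASVs
   (`cag_abundance`), conserving reads exactly.

### The split-test null: a genuinely open design point

The clade being tested is *chosen by Ward clustering of the very distances
being tested*, so permuting group labels while keeping the observed split
fixed produces a null in which the observed pseudo-F is, by construction,
extreme: on completely structureless data that naive test declares nearly
every node significant, and recursion only stops when clades become too
small to test. We keep that variant available (`split_null = "labels"`)
for comparison, but the default re-selects the split under each
permutation so that observed and permuted statistics are exchangeable when
the node carries no structure:

* `split_null = "data"` (default when the rCLR matrix is supplied):
  permute each feature's values independently across samples, recompute
  the repeated-observations correlation distance among the node's members,
  re-run Ward, and score the re-selected two-way split. This destroys
  co-abundance while preserving each feature's marginal distribution and
  missingness pattern. For the paired two-samples-per-subject design the
  correlation matrix reduces exactly to crossproducts of per-subject
  observation differences, which makes the permutation loop three BLAS
  products per draw (`src/split_test.cpp`); designs with more observations
  per subject fall back to a general loop.
* `split_null = "ward"` (default for distance-only input): shuffle the
  node's off-diagonal distances and re-run Ward; exact when the distances
  themselves are exchangeable.

With either null, structure-free inputs end as a single CAG at the nominal
rate, and planted blocks are recovered cleanly (the acceptance suite
checks both). Nodes smaller than `min_split_n = 5` members are declared
CAGs untested: a two-group PERMANOVA with singleton-sized groups has no
usable permutation resolution. Because the cutoff is 0.001, any run needs
`n_perm >= 1000` for a split to be acceptable at all; the default is 9999,
and the test suite uses 1199 (permutation floor 1/1200) to keep runtimes
proportionate to its problem sizes.

No multiplicity correction is applied across the consecutive split tests;
the procedure uses a fixed per-split cutoff, and we document rather than
"fix" this, since the cutoff's stringency (0.001) is part of the method's
definition.

## The genus comparator and the reduction ledger

`aggregate_genus` sums classifiable ASVs into genera keyed by the full
lineage string down to genus (bare genus names would merge homonyms across
families). An ASV is unclassifiable when its genus rank is absent, empty
(`g__`), or a placeholder token (`uncultured...`, `unclassified...`;
configurable). Reads of the genus table plus excluded reads equal the
input total exactly — the ledger depends on this identity.

`reduction_ledger` tracks both methods through four reduction levels —
feature selection, aggregation, treatment-responding variables,
health-relevant variables — reporting variable counts, reads retained,
percent of total reads (half-up rounding, two decimals with a one-decimal
display option) and sparsity. All percentages share one denominator: the
rarefied ASV table's grand sum.

## Ordination, concordance and information loss

Diversity and ordination use the field's standard tools: Shannon index in
bits (log2, the convention of the QIIME2 ecosystem; natural log optional),
Bray–Curtis dissimilarity, and principal coordinates via the
double-centred `-d^2/2` eigendecomposition with negative eigenvalues
reported but excluded from coordinates. Group differences use Anderson's
PERMANOVA with seeded permutations and exhaustive enumeration of two-group
relabelings when those number no more than `n_perm`; pairwise tests are
Benjamini–Hochberg adjusted.

How much community structure survives aggregation is measured by
Procrustes superimposition of the aggregated ordination onto the
full-resolution ASV ordination: the residual `m12^2` after centering,
unit-scaling and optimal rotation, with PROTEST permutation significance
(999 permutations by default). The **information-loss score** is the ratio
of the genus-level to the CAG-level `m12^2`; above 1, the genus summary
lost more structure. When the CAG-level residual is zero the ratio is
undefined and reported as such, not as infinity. Ordinations are compared
on their shared count of positive axes by default; a two-axis mode mirrors
plot-level comparisons, and both choices are recorded in the result.

## Marker discovery

`boruta` implements shadow-feature all-relevant selection around a random
forest: each iteration appends a permuted copy of every undecided feature,
fits a forest (500 trees by default), and scores features by the mean
decrease in accuracy normalised to a Z-score; a feature "hits" when it
beats the best shadow. Hit counts are tested against the fair-coin null
(two-sided binomial, Bonferroni across the starting features, alpha 0.01);
features are confirmed or rejected as evidence accumulates, and whatever
is undecided after 100 iterations stays tentative rather than being
force-resolved. Selected features are validated by repeated stratified
cross-validation (5x5 by default) of a random-forest classifier with
out-of-fold probabilities summarised as a trapezoidal ROC/AUC, and
screened against phenotypes by Spearman correlation with BH correction
across the whole feature-by-phenotype grid. `health_relevant` intersects
Boruta confirmation with phenotype significance.

At these sample sizes an important caveat applies: a noise feature that
happens to correlate with the labels *in this sample* is genuinely
informative in-sample, and Boruta will sometimes confirm it (one to two
such features per 50-noise run at n = 80 in our calibration). That is a
property of all-relevant selection on small n, not an implementation
artefact, and is why confirmed markers are further screened against
independent phenotypes.

## Rhythm detection

`ejtk` tests each series against a family of phased cosine references at a
fixed 24-h period (phase grid at the 6-h sampling interval by default,
deduplicated by rank pattern). The statistic is the maximum Kendall tau-b
over the family — replicates within a timepoint share the reference value
and are handled by tau-b's tie correction, not by averaging — and
significance comes from permuting values across all time-replicate slots.
Being rank-based, the p-value is invariant to monotone transforms of the
series. We restrict the reference family to symmetric cosines: only the
period is fixed by the study design, and an asymmetry search would
multiply the reference family without a design reason; the empirical
p-value machinery would accommodate one unchanged. Group scans
(`rhythm_scan`) use each group's own samples only.

## The synthetic community generator

`simulate_community` draws study-shaped data with known truth: per-block
latent log-normal factors shared within blocks (loading
`within_block_corr`), subject-block random intercepts (SD 0.5) creating
the repeated-measures structure the correlation estimator targets, group
log-fold effects applied at the final timepoint, multinomial sampling at a
fixed library size, and an optional uniform dropout applied to the
sampling probabilities so per-sample totals still sum exactly to depth
while overall sparsity lands within five points of its target. The
log-normal-plus-multinomial construction was chosen over a
Dirichlet-multinomial because it gives direct control of the pairwise
correlation structure — the very thing the pipeline estimates.

Default scales mirror a four-arm mouse study: 4 groups (NFD/HFD crossed
with ad-libitum/TRF) x 15 subjects x 2 occasions (120 samples), 1100
features with 34 planted blocks of 8 forming the prevalent core and the
rest rare background, 80% sparsity, library size 25 000 (so rarefying to
18 000 is a real operation), 40% of ASVs unclassifiable at genus level
(drawn systematically along the abundance ranking so the unclassifiable
*read share* tracks the fraction as well), and a time course of 8
timepoints (every 6 h over 48 h) x 4 replicates. Phenotypes are linear in
block relative abundances plus Gaussian noise, emulating fasting glucose
and an OGTT area-under-curve.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: phylogenetic correlation among taxa,
overdispersion beyond the multinomial, batch and cage effects (cage ids
are emitted but carry no planted effect), non-cosine rhythm shapes, and
taxonomy errors. Recovery results on synthetic data bound what the
pipeline can do when its model assumptions hold; they do not certify
performance on any particular real dataset.

## Problem sizes used by the tests and acceptance script

Guild recovery is exercised at 60 samples (30 subjects x 2) and depth
20 000 with 4 planted blocks of 15 features (within-block loading 0.7) and
8 blocks at 300 features (loading 0.6); the split walk uses 1199
permutations per node at alpha 0.001. Rhythm calibration uses 8 timepoints
x 3 replicates, 199 permutations, 1000 null series; power uses
amplitude/noise 2. Boruta calibration uses n = 80 samples, 5 planted + 50
noise features, 100 iterations, 300 trees. The acceptance script runs the
same measurements at reduced seed counts and one moderate full-pipeline
study (24 subjects, 120 features, 8 blocks). These sizes are the package's
own reference conditions, chosen once to characterise each component with
useful statistical resolution.

## Known limitations

* The split test's selection-aware null is a permutation scheme, not an
  exact theory of post-clustering inference; its calibration is
  demonstrated empirically in the test suite.
* Undefined correlations entering the distance matrix as 0 slightly bias
  sparse-feature distances toward 1; prevalent-feature analyses are
  insensitive to this, which is one more reason the prevalence filter
  precedes the correlation step.
* `permanova` enumerates exhaustively only for two groups; k-group tests
  always sample.
* The Shannon default (bits) differs from vegan's natural-log default;
  compare like with like when mixing tools.
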