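# scmetaboscape

Tools for charting **metabolic heterogeneity in tumour single-cell RNA-seq
data** and carrying a metabolic signature through to patient survival.
The package is aimed at computational biologists who want the complete
chain — from a UMI count matrix and a metabolic gene-set collection (GMT)
to cell-type pathway activities, malignant-cell metabolic subclusters,
marker signatures, and a survival-stratified bulk cohort — as composable,
tested R functions rather than a one-off script collection. Every stage
can also be exercised end-to-end on synthetic data with planted ground
truth, which is how the package validates itself.

## The statistics at the core

**Cell-type pathway activity.** For gene *g* and cell type *t*, the
relative expression is

    r_gt = mean_gt / ( (1/T) * sum_t' mean_gt' )

(the gene's mean in *t* against the unweighted average over all *T*
types; 1 = parity). The activity of pathway *P* in type *t* is the
weighted mean

    score(t, P) = sum_{g in P} w_g r_gt / sum_{g in P} w_g ,
    w_g = 1 / (number of pathways containing g)

so genes shared across pathways are down-weighted. Significance comes
from a permutation null: cell-type labels are shuffled (within
condition), the whole scoring pipeline is recomputed, and the two-sided
deviation |score − 1| is compared against the permuted deviations with
the +1-corrected empirical p-value, then Benjamini–Hochberg adjustment
across the (pathway × cell type) table.

**Per-cell enrichment.** Each gene's expression is converted to a
kernel-smoothed empirical CDF statistic across cells (Gaussian kernel,
bandwidth SD/4), rank-transformed within each cell with the symmetric
weight |G/2 − rank + 1/2|, and each gene set is scored by a weighted
Kolmogorov–Smirnov random walk (magnitude-difference statistic). These
per-cell scores feed Euclidean/complete-linkage clustering (cut at
k = 2) to split malignant cells into **high** and **low** metabolic
subclusters, named by their mean scores.

**Survival stratification.** A marker signature extracted from the
high/low contrast (Wilcoxon markers at min.pct = 0.25, |log2FC| ≥ 0.25;
top-N by fold change among q < 0.05) scores a bulk cohort with the same
per-sample enrichment statistic. A maximally selected log-rank cutpoint
(minprop = 0.1) splits the cohort; Kaplan–Meier/log-rank and a
multivariate Cox model (Efron ties) quantify the prognosis difference,
with an optional permutation-based selection-adjusted p for the
cutpoint's maximal statistic.

## A worked example

```r
library(scmetaboscape)

# synthetic tumour with a planted high/low metabolic split
sim <- plant_metabolic_split(simulate_counts(simulation_config(seed = 1)))
sim$counts
#> ExpressionMatrix: 2000 genes x 2000 columns [counts]
#> annotation: sample, condition, cell_type

# normalize and score pathway activity per cell type
norm <- normalize_counts(sim$counts, size_factors(sim$counts, "deconvolution"))
act  <- pathway_scores(relative_expression(celltype_means(norm)), sim$pathways)
act  <- permutation_test(subset_expr(norm, genes = sim$pathways$universe),
                         sim$pathways, act, n_perm = 500, seed = 1)
act
#> ActivityTable: 50 pathways x 4 cell types (200 defined)
#> permutation p-values present (n_perm = 500)

# split malignant cells on per-cell enrichment scores
mal <- which(norm$annotation$cell_type == "malignant")
v   <- as.matrix(sim$counts$values[, mal])
lg  <- ExpressionMatrix(log1p(sweep(v, 2, colSums(v), "/") * 1e4),
                        norm$annotation[mal, ], units = "lognorm")
sc    <- gsva_scores(lg, sim$pathways)
split <- label_high_low(hierarchical_split(sc, k = 2), sc)
table(split$labels, sim$truth$metabolic_group[colnames(v)])
#>        high  low
#>  high   500    0
#>  low      0  500

adjusted_rand_index(split$labels, sim$truth$metabolic_group[colnames(v)])
#> [1] 1
```

The confusion table says the planted high/low programme was recovered
exactly (all 1,000 malignant cells assigned to their true group;
adjusted Rand index 1). Continuing to markers, a signature and survival:

```r
de  <- find_markers(lg, split$labels, contrast = c("high", "low"))
sig <- top_n_signature(de, n = 8)

bulk  <- simulate_bulk_survival(375, sig$genes, hazard_ratio = 2, seed = 1)
coh   <- survival_cohort(score_bulk(bulk$expression, sig),
                         bulk$cohort$time, bulk$cohort$event)
cp    <- optimal_cutpoint(coh, minprop = 0.1)
km    <- km_logrank(coh, cutpoint = cp$cutpoint)
cp; km$p
#> CutpointResult: cutpoint -0.05645, |z| = 6.335 (n = 196 high / 179 low)
#> [1] 2.379161e-10
```

Here the cohort's planted score threshold (the latent-score median,
which maps to an enrichment score near 0) is recovered at −0.056 and
the two groups' survival separates at a log-rank p of 2.4e-10. `run_pipeline(pipeline_config(seed = 1), "out/")` chains all
stages and writes TSV outputs plus a JSON manifest of content hashes.

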