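# endoprot

Molecular endotype discovery from serum proteomics.

Inflammatory skin diseases such as moderate-to-severe atopic dermatitis (AD)
are clinically heterogeneous, and a growing body of work stratifies patients
into *molecular endotypes* — subgroups defined by circulating protein
profiles rather than by clinical appearance. `endoprot` packages the full
analysis workflow for such studies, built around Olink-style NPX panels
(relative protein abundance on a log2 scale, samples × ~1,000 assays):

1. **QC** — coefficient-of-variation marker filtering
   (CoV% = 100·sd/mean on linearised values), missing-value policy,
   per-marker z-scaling.
2. **Endotype discovery** — k-means with k-means++ restarts and a WCSS
   scree; a *stability* protocol that perturbs the data by adding/removing
   healthy controls and cross-tabulates patient assignments; a
   *reproducibility* protocol that repeats a random split, runs k-means
   independently on both parts, trains a random-forest prediction rule on
   the training part and scores permutation-matched agreement on the
   testing part (100 iterations, medians reported); exact t-SNE for
   visualisation with 95% cluster ellipses.
3. **Differential expression** — per-protein linear models with age/sex
   covariates, empirical-Bayes variance moderation
   (s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g), prior estimated by the
   log-variance moment method), BH adjustment, strict
   |log2FC| > 1.2 & adjusted p < 0.05 thresholds, and the three-way Venn
   grouping of DE proteins into *Upregulated-AD*, *Stepwise* and *Unique*
   sets.
4. **Co-expression networks** — signed WGCNA-style analysis:
   a_ij = ((1+cor)/2)^β with β chosen by scale-free topology fit,
   topological overlap, module detection on the TOM dendrogram with
   kME-refinement and eigenprotein merging, module eigenproteins (ME),
   kME/hub proteins, module–trait correlation with BH across the grid, and
   hub-centred network export (GraphML/edge list).
5. **Enrichment** — preranked GSEA on protein–ME correlation rank scores
   (weighted running-sum statistic, gene-set permutation null) and
   hypergeometric overrepresentation against the assayed-protein universe;
   gene sets supplied as GMT.
6. **Clinical prediction** — random-forest prediction of endotype
   membership from clinical/laboratory data with dual importance measures
   (permutation and Gini), separating-threshold scans, and per-cluster
   Wilcoxon / chi-squared comparisons.

Because the clinical-trial data such studies use are access-controlled, the
package ships a **synthetic-cohort generator** (`simulate_cohort`) that
reproduces the statistical skeleton of a published endotyping cohort — 15
controls plus two patient endotypes of 31 and 42, 1,248 proteins in ten
co-expression modules (536…22), a 169-protein disease signature containing
a 40-protein stepwise subset and a 16-protein endotype-1-only subset, and
Table-style clinical traits coupled to module activity — with complete
ground truth for recovery testing.

## Worked example

```r
library(endoprot)

cohort <- simulate_cohort(default_config())
cohort$npx
#> npx_matrix: 88 samples x 1248 proteins (73 AD, 15 HC)

qc <- cov_filter(cohort$npx, threshold = 20)
qc$report
#> CoV QC (linear scale, keep-above 20%): 1248 -> 1248 proteins

Zp <- zscale(qc$npx$values[qc$npx$group == "AD", ])
fit <- kmeans_fit(Zp, k = 2, restarts = 25, seed = 1)
fit
#> k-means fit: k=2, sizes 42/31, WCSS 59092.454

adjusted_rand_index(fit$assignments,
                    cohort$truth$cluster_label[qc$npx$group == "AD"])
#> [1] 0.891924

rep <- reproducibility(Zp, k = 2, iterations = 20, seed = 1)
rep
#> reproducibility over 20 iterations (split 70/30): median train 100.0%, median test 95.5%

Z <- zscale(qc$npx)$values
power <- pick_soft_power(Z)$power   # falls back to the signed default, 12
mods <- detect_modules(tom_similarity(signed_adjacency(Z, power)), Z)
mods
#> module assignment: 10 modules (+1 grey)
#> turquoise      blue     brown    yellow     green       red     black
#>       536       290       178        58        37        37        34
#>      pink   magenta    purple
#>        28        27        22
```

The two planted endotypes are recovered almost exactly (Rand index 0.89 for
this seed; the median across seeds exceeds 0.9), the split-retrain protocol
confirms they are reproducible, and the module detector returns the ten
planted co-expression modules at their exact sizes. The whole pipeline
(`run_pipeline(pipeline_config(simulate = default_config(), seed = 1))`)
runs end-to-end in about a minute on one CPU and writes a machine-readable
report bundle (tables, GraphML hub networks, `report.json`).

One scale difference from real cohorts is intentional: the generator's
endotype contrast must dominate total variance for unsupervised recovery to
be possible, so the endotype-vs-endotype DE contrast flags whole disease
modules rather than a ~56-protein subset; see the methods vignette
(`vignettes/endotyping-methods.Rmd`) for the reasoning.

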