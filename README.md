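# rgcsubtypes

Subtype discovery, laterality statistics, and transcription-factor
combinatorics for retinal ganglion cell (RGC) single-cell RNA-seq.

RGCs — the retina's output neurons — comprise dozens of transcriptomically
distinct subtypes, most without a known unique marker. This package
implements, as a tested and reusable R pipeline, the analysis style used to
classify droplet scRNA-seq profiles of purified RGCs into subtypes and to
characterize what distinguishes them. It is aimed at analysts who want the
individual steps as composable functions with explicit contracts, plus a
synthetic-data generator with planted ground truth to validate every step
end to end.

## The method

Starting from a 10x-style UMI count matrix (genes × cells MTX with gene and
barcode TSVs, the barcode file carrying the eye of origin):

1. **QC** — cells below a genes-detected cutoff (the low-coverage
   sub-peak) are removed.
2. **Normalization** — normalized expression
   `NE = log2(x · M / T + 1)`, where `T` is the cell's total UMIs and `M`
   the median of totals across cells. All thresholds below are in NE
   units.
3. **Two-round clustering** — the 1000 most over-dispersed genes
   (variance/mean of NE; sex genes excluded), 3-D Barnes–Hut t-SNE, and
   DBSCAN (`eps = 5.0`, `minpts = 15`; noise → cluster 0). Round-1
   clusters dominated by non-RGC contaminant markers are excluded, and the
   remaining cells are re-embedded and re-clustered.
4. **Unique markers** — genes expressed > 1.8-fold (mean NE) above *every*
   other cluster and > 0.05 NE, with dual-test significance tiers
   (t-test + Mann–Whitney U, worst-case p over all comparisons).
5. **Laterality** — Pearson χ² over the eye × cluster table (df = K−1),
   Bonferroni-corrected two-proportion z-tests per cluster, and
   mirror-symmetry correlations of eye-specific cluster transcriptomes.
6. **Hierarchy** — Ward linkage over Chebyshev distances between cluster
   profiles, cut into 4 superclusters and 10 intermediate subpopulations
   (ISPs), with per-member-cluster verification of ISP-enriched genes.
7. **TF combinations** — TFs binarized per cluster (> 0.5 NE and > 2× their
   cross-cluster mean), all combinations up to 5-way enumerated, and
   minimal combinations whose joint (AND) pattern marks exactly one
   cluster reported, cross-referenced against a relaxed 1.5-fold run;
   supported by mixed-design repeated-measures interaction ANOVA.

The synthetic generator (`sim_config()` + `generate()`) plants all of this
structure — nested cluster/ISP/supercluster hierarchy, per-cluster markers
at a chosen NE fold, TF combinations unique only jointly, per-cluster eye
imbalance, a low-coverage sub-peak, and a contaminant fraction — and
returns the full ground truth for recovery testing.

## Worked example

```r
library(rgcsubtypes)

g  <- generate(sim_config(seed = 1))          # 3000 cells x 2000 genes, 8 planted subtypes
qc <- filter_low_coverage(g$counts, min_genes = 600)
em <- normalize_ne(qc$counts)
tr <- two_round(em, g$truth$panels, seed = 1) # t-SNE + DBSCAN, contaminant removal
tr$clusters
#> rgc_clusters: 2586 cells in 8 clusters; 0 unassigned (cluster 0)
round(100 * tr$excluded_fraction, 1)
#> [1] 3.9
prof <- cluster_profile(tr$em, tr$clusters)
mk <- unique_markers(tr$em, tr$clusters, prof)
head(mk[, c("gene", "cluster", "min_fold", "expr", "tier")], 3)
#>     gene cluster min_fold     expr   tier
#> 1 G00613       1 2.427944 2.360629 strict
#> 2 G01477       1 2.409465 2.479757 strict
#> 3 G00436       1 2.371546 1.452202 strict
combos <- cross_reference(prof, g$truth$panels$tf, max_k = 3)
```

The clustering recovered all 8 planted subtypes (adjusted Rand index 0.998
against the planted labels) with no noise cells; 3.9% of round-1 cells were
excluded as contaminant clusters (the planted contaminant fraction is 4%);
the top marker of cluster 1 exceeds every other cluster by 2.4-fold in mean
NE at the strict significance tier.
`combos` lists the TF sets whose joint enrichment pattern is unique to one
cluster at both the 2-fold and 1.5-fold binarization thresholds —
including every planted combination.

`run_pipeline(pipeline_config(), out_dir)` chains all stages and writes
CSV/TSV/JSON/newick artifacts plus a log; reruns with the same seed are
byte-identical. A thin command-line wrapper is installed at
`inst/scripts/rgc-pipeline.R`.

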