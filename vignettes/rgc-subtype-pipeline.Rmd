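---
title: "Methods: subtype discovery, laterality, and TF combinatorics for RGC scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype discovery, laterality, and TF combinatorics for RGC scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rgcsubtypes` implements a droplet single-cell RNA-seq analysis for
classifying retinal ganglion cells (RGCs) into transcriptomic subtypes and
characterizing what distinguishes them: uniquely enriched marker genes,
left/right-eye laterality, a diversification hierarchy from population to
intermediate subpopulations (ISPs) to terminal subtypes, and transcription
factors (TFs) whose *joint* enrichment — but not any member alone — marks a
single subtype.  Because a real droplet experiment of this kind cannot be
regenerated at test time, the package also ships a first-class synthetic
count generator with planted ground truth for every one of those
structures, so the entire pipeline is exercised end to end with known
answers.

# Normalization and quality control

The unit of analysis is normalized expression (NE).  With $x_{gc}$ the UMI
count of gene $g$ in cell $c$, $T_c = \sum_g x_{gc}$ the cell total and $M$
the median of all $T_c$ (mean of the two middle values when the number of
cells is even — the convention is stated explicitly because it matters for
exact reproduction of worked examples):

$$NE_{gc} = \log_2\!\left(\frac{x_{gc}\, M}{T_c} + 1\right).$$

Zero counts map exactly to NE 0, and NE is strictly increasing in the count
within a cell, so within-cell gene rankings are preserved.  All downstream
thresholds (0.05 NE for marker candidacy, 0.5 NE for TF binarization, etc.)
are in these units.

Cells below a genes-detected cutoff are removed *before* normalization
(`filter_low_coverage`), because removing them afterwards would change $M$.
The default cutoff of 3000 genes suits full-transcriptome data averaging
~5000 genes per cell; for the reduced desk-scale gene spaces used in tests
the cutoff scales down proportionally (600 genes at a 2000-gene space, 200
at 700), chosen to sit between the low-coverage sub-peak and the 1st
percentile of the healthy cells.

# Two-round embedding and density clustering

Gene selection takes the `n = 1000` most over-dispersed genes, with
dispersion defined as variance/mean of NE among genes with positive mean
NE.  Sex-specific genes are excluded from selection (they track animal sex,
not cell identity) but are retained in the data for downstream analysis.

Embedding is Barnes–Hut t-SNE in **three** dimensions (perplexity 30, 1000
iterations, theta 0.5, PCA initialization to 50 components; all recorded in
the embedding object since "default parameters" are tool-version
dependent).  Density clustering is classical DBSCAN with `eps = 5.0` and
`minpts = 15`, run on all three embedding dimensions — `eps` is in
embedding units and only makes sense there.  DBSCAN noise becomes cluster
0, "cells that did not fit uniquely to any one cluster"; clusters are
renumbered 1..K by decreasing size, since the numbering is otherwise
arbitrary.  No DBSCAN implementation is available among this package's
dependencies, so the package carries its own: grid-binned neighbor lookup
(bins of side `eps`, candidates from the 27 adjacent bins) with classical
BFS cluster expansion, `minpts` counting the point itself.  Its behavioral
contracts — separation of point masses, all-noise degenerate input,
invariance to input order up to the renumbering rule, minimum cluster size
— are tested directly.

Round 1 clusters everything that passed QC; clusters whose mean NE over a
contaminant (non-RGC) marker panel exceeds their mean NE over the pan-RGC
panel are flagged as contaminant clusters (our operationalization of
"highly expressed non-RGC markers"), and their cells are excluded.  Round 2
re-selects over-dispersed genes on the remaining cells (the selection
changes once contaminants are gone), re-embeds with a derived seed, and
re-clusters.  The excluded fraction is reported against the round-1 cell
count.

# Subtype markers

`unique_markers` emits gene/cluster records where the cluster's mean NE
exceeds **1.8-fold** the mean NE of *every* other cluster (strict
inequality) and exceeds **0.05 NE** at home.  Folds are ratios of mean NE
values — the same unit in which the TF rule below is phrased; a
linear-scale variant would first de-log, and is deliberately not the
default so that one fold convention runs through the whole package.  When
the best other cluster has mean 0, the fold criterion counts as satisfied
provided the home mean clears the expression floor.

For up to the top 5 fold-ranked candidates per cluster, per-comparison
two-tailed Welch t-tests and Mann–Whitney U tests on per-cell NE values are
run against every other cluster, and the *worst* p across the K−1
comparisons is kept.  Tiers: `strict` (both tests ≤ 0.05), `relaxed`
(t ≤ 0.05, MWU ≤ 0.1), `weak` (exactly one test ≤ 0.05 and the other
> 0.1), `ns` otherwise.  Candidates beyond the top 5 are emitted untested
(`tier = NA`).  No multiple-testing correction is applied to these
per-comparison thresholds — the rule is deliberately per-comparison; a
Bonferroni variant is a one-liner on the returned table.  Clusters smaller
than `small_cluster_min` (default 30 cells) have their records flagged
`small_cluster` rather than suppressed: their p-values are underpowered,
which the analyst should see, not have hidden.

The homogeneity census (`homogeneity_census`) classifies each gene, at each
expression threshold, as homogeneous (max/min cluster-mean ratio ≤ 1.5)
or non-homogeneous, separately for TFs and other genes; a gene enters the
count at threshold $\tau$ when its *maximum* cluster mean exceeds $\tau$
(the inclusion rule at a threshold is not fully pinned down by the field's
usage; max-cluster-mean is the choice here, asserted against a brute-force
recount in the tests).  Percentages are normalized within each of the four
categories relative to the lowest threshold.

# Laterality

Counts of left- and right-eye cells per cluster (cluster 0 and unknown-eye
cells excluded; eyes are never imputed) feed three analyses:

* Pearson $\chi^2$ on the 2×K table, df = K−1 (39 for a 40-subtype atlas).
* Per-cluster two-proportion z-tests of the cluster's share of each eye's
  cells, with pooled variance and Bonferroni correction over the K
  clusters.  The published analysis cites a statistics-suite "comparison of
  column proportions" without formulas; the pooled two-proportion z is the
  textbook operationalization, and at K = 2 it satisfies $z^2 = \chi^2$
  exactly, which the tests assert.  Clusters with fewer than 2 cells are
  reported untestable.
* Mirror symmetry: per-cluster eye-specific mean-NE profiles; Pearson
  correlations of same-cluster left/right pairs versus all cross-cluster
  left/right pairs, compared by an independent two-sample t-test.

# Hierarchy and ISPs

The subtype tree is Ward linkage (`ward.D2`) over Chebyshev (maximum
coordinate) distances between cluster mean-NE profiles.  Ward over a
non-Euclidean distance is a heuristic, but it is the canonical pairing in
this analysis style; a maximum-distance + complete-linkage alternative is
available behind the `linkage` argument for heatmap-style dendrograms.
Superclusters and ISPs are horizontal cuts of the same tree (`cutree` at
k = 4 and k = 10 by default) — cuts of one tree are automatically nested,
and the cut counts are parameters, not auto-detected: the hierarchy depth
is a modeling commitment, not an estimate.

ISP-level enrichment merges each ISP's clusters into one pseudo-cluster,
applies the unique-enrichment rule across ISPs, then re-verifies each candidate
in every member cluster against the best non-ISP cluster — automating the
manual confirmation step such analyses otherwise require, because a merged
average can be carried by a subset of member clusters.

# TF combinatorics

`binarize` scores a TF 1 in a cluster when its mean NE is > 0.5 **and**
more than 2× its unweighted mean across cluster means (cluster-level, not
cell-weighted: the matrix is built from profiles).  Rows that are all 0 or
all 1 are dropped as uninformative.  `unique_combos` enumerates subsets up
to size 5 in increasing size and lexicographic order; a subset whose
element-wise AND pattern has exactly one 1 is a unique signature of that
cluster.  Minimality: a combination containing an already-unique proper
subset is not reported (the AND pattern of a superset of a unique combo can
only be that same single cluster, so it adds nothing).  All-zero patterns
prune their supersets, which keeps the enumeration lazy; correctness
against an unpruned exhaustive oracle with an explicit minimality filter is
asserted on hundreds of random matrices.  `cross_reference` repeats the
procedure at a relaxed 1.5-fold binarization and keeps only combinations
found at both thresholds — the relaxed run admits marginal enrichments, so
a signature that gains a second cluster there was fragile and is dropped.

Statistical support for a combination is a mixed-design repeated-measures
ANOVA per cluster pair: TF identity is the within-subject factor, cluster
the between-subject factor, sphericity assumed (univariate `aov` with an
`Error(cell/tf)` stratum); the headline number is the TF×cluster
interaction p.  `p_focal` averages the interaction p over focal-vs-other
pairs, `p_between_others` over pairs among non-focal clusters.  The exact
repeated-measures layout used in the original statistics suite is
ambiguous; this operationalization is documented as ours and is *not*
expected to reproduce any published per-combination p-value exactly.
Single-TF signatures get `applicable = FALSE`: their support is a plain
differential-expression question, not an interaction.

# The synthetic generator

`sim_config()` describes the generative conditions; `generate()` draws the
data.  The model:

* Gene baseline count means are log-normal (meanlog log 0.8, sdlog 1.0).
* Supercluster, ISP, and cluster multiplicative offsets (log-normal, sdlog
  0.25 / 0.18 / 0.08) are applied in nested fashion, so within-ISP clusters
  correlate more than across-ISP ones.
* Counts are negative-binomial (dispersion 0.15) with per-cell log-normal
  size factors (sdlog 0.3) — the standard noise model for UMI data.
* **Cluster markers**: disjoint gene sets per cluster, drawn from a
  low-moderate baseline (meanlog log 0.6, sdlog 0.4).  The planted fold is
  specified in mean-NE-ratio units — the unit the enrichment rule
  thresholds — and the home-cluster count mean is back-solved numerically
  (expected value of $\log_2(x+1)$ under the NB law, inverted with
  `uniroot`).  Planting the fold on raw count means instead would be
  silently eroded by the log transform: a 2.5-fold count difference
  realizes only ~2.0-fold in mean NE, which sampling noise then pushes
  below the 1.8 detection threshold, making the planted truth
  unrecoverable by construction rather than by any fault of the method.
* **ISP and supercluster markers**: genes enriched (NE folds 4 and 6) in
  every member cluster of a group with ≥ 2 clusters — the synthetic
  analogue of subpopulation markers such as ooDSGC or ipRGC genes.  Without
  them a Chebyshev-distance tree cannot see the hierarchy: the max-gene
  distance between any two clusters is dominated by their private cluster
  markers, which are equally different for every pair.
* **TF combinations** are planted pattern-first: for an $m$-way combination
  targeting cluster $k$, a covered set of non-focal clusters is partitioned
  into $m$ groups and member $i$ is enriched in $k$ plus everything except
  group $i$.  Every proper sub-combination keeps a group (not unique); the
  full intersection is exactly $\{k\}$.  The covered set is capped so each
  member stays enriched in fewer than ~44% of clusters and therefore
  survives the 2-fold binarization rule — beyond that cap, a TF's enriched
  mean cannot exceed twice its own cross-cluster mean, and planting would
  be infeasible (requested combinations that violate this raise an
  explicit error).  The cap also bounds feasible combination sizes: with 8
  clusters, up to 3-way; 4- and 5-way plantings need atlas-scale cluster
  counts.
* **Laterality** is Bernoulli per cell with a per-cluster right-eye
  probability; **low-quality cells** have their size factor scaled by 0.2,
  producing the sub-peak the genes-per-cell filter removes; **contaminant
  cells** are drawn from an independent baseline with the contaminant
  panel high and the pan-RGC panel low.

Defaults are desk-scale — 3000 cells × 2000 genes × 8 clusters in 4 ISPs
and 2 superclusters — sized so the full two-round t-SNE/DBSCAN recovery
study runs in minutes on one CPU; `sim_config_full()` mirrors a full atlas
(6225 cells, 40/10/4).  Effect sizes have no published counterpart, so they
were calibrated once against the recovery criteria the generator exists to
support (marker fold 2.5, contaminant fraction 4%, low-quality fraction
10%, 2:1 laterality for power studies) and are not revisited per run.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: doublets, ambient RNA, batch and
chemistry effects, gene–gene correlation beyond the block structure of the
planted hierarchy, mean–dispersion trends, and continuous or immature cell
states (every synthetic cell belongs to exactly one cluster; real cluster-0
cells may be a biological continuum).  Recovery results certify the
*implementation* against its specification, not the biological validity of
t-SNE + DBSCAN subtype discovery.

# Numerical and reproducibility choices

* Every stochastic step (generation, t-SNE) takes an explicit integer seed
  and restores the caller's RNG state; round 2 of clustering uses
  `seed + 1`.  The same config is bit-identical across runs.
* Ties in over-dispersion ranking break by gene identifier; cluster
  renumbering ties break by first occurrence; `cutree` labeling follows
  leaf order — all deterministic.
* Degenerate inputs are errors, not guesses: zero-total cells name the
  offending barcode, an all-removed QC filter aborts, K < 2 refuses fold
  computations, transposed MTX input is rejected rather than silently
  fixed.
* Worked-example identities (the NE = 4.0 two-cell case, z² = χ² at K = 2,
  the 2.36 + 4.85 = 7.21 accounting) are asserted exactly, not to a
  tolerance.

# Problem sizes used in the test suite

The recovery studies run at the desk scale above: five seeds of the full
two-round clustering study, one 5000-cell generation for the marker-fold
contract, a 4000-cell × 40-cluster profile for hierarchy recovery and for
the interaction-ANOVA contrast, 100 random 20×10 matrices for the
combinatorial oracle, and 50 + 200 replicates (3000 cells each, 130-gene
expression space) for laterality power and size.  These sizes are the
package's chosen trade-off between statistical resolution and a test suite
that a contributor will actually run.

# Known limitations

* t-SNE + DBSCAN is the implemented design; graph-based clustering
  (Louvain/Leiden) and UMAP are out of scope, as are batch integration,
  doublet detection, and ambient-RNA correction.
* The repeated-measures ANOVA layout is our reading of an under-specified
  procedure (see above).
* `eps = 5.0` is meaningful only in t-SNE embedding units; embeddings of
  very different scale (tiny cell numbers, different perplexity) may need
  a different radius.
* Chebyshev distance is sensitive to single extreme genes; profiles with
  heavy outliers may want the complete-linkage alternative or prior gene
  filtering.
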