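---
title: "From gland zones to fiber layers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gland zones to fiber layers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ampulla` infers where silk proteins are made and where they end up: which
cell type and glandular zone of the major ampullate gland produces each
fiber protein, and which concentric fiber layer that protein forms. This
vignette documents the statistical models, the tunable parameters, the
synthetic data generator that stands in for the wet-lab assays, and the
design choices made where several defensible options existed.

## The inference chain

The pipeline runs five stages (`run_pipeline()` orchestrates them):

1. **Gland gene set** from bulk RNA-seq of tail, sac, duct, head, body and
   other-gland samples.
2. **Single-cell** clustering and marker analysis, anchored to the gland
   parts via gene-set overlap.
3. **Spatial** zone analysis: proximo-distal ordering of zone A by
   cross-section perimeter, and cell-type deconvolution of spots.
4. **Proteomics**: spectral-count quantification and the four-criteria
   identification of fiber-constituent proteins.
5. **Layer inference**: urea solubilization gradients, the dissolved-fiber
   control, H&E matching of lumen layers to zones, and the final
   zone-to-layer model.

## Gene-set filter

Counts are prefiltered to genes with TPM > 4 in at least one sample, then
transformed by a variance-flattening transform: median-of-ratios size
factors followed by `log2(count/sf + 1)`. This transform plays the
variance-stabilizing role in the filter; it is intentionally simple and its
output is read in log2 units throughout.

Steps 1–2 are sign filters: PCA across the relevant samples, PC1 oriented so
that the gland-containing group has a positive mean score, genes with a
strictly positive PC1 loading retained. Step 2 accepts a rescue list so that
independently curated silk genes can be force-retained, mirroring manual
curation practice.

Step 3 computes PCA on the tail/sac/duct samples and measures each gene's
Euclidean distance from the origin in the (PC1, PC2) loading plane.
**Loading convention.** Loadings are on the covariance scale — the rotation
matrix scaled by the component standard deviations, i.e. the covariance
between a gene's log2 values and the unit-variance component score. A
loading of 0.33 therefore means about 1.26-fold of component-aligned
variation. We deliberately did not use correlation-scale loadings: with 15
samples the null correlation of an uninformative gene has a standard
deviation of roughly `1/sqrt(n-1) ≈ 0.27`, so no fixed cutoff can separate
signal from noise on that scale. On the covariance scale the null loading
scale is set by the replicate noise (about 0.12 log2 units per component at
NB dispersion 0.1 and five replicates), and the default cutoff of 0.33
sits several null standard deviations above it while remaining below the
planted genes' structured variation (0.45–1.0). The cutoff is exposed as a
tunable (`cutoff`, `distance_cutoff` in the pipeline config) because its
absolute value is tied to this convention.

Retained genes are labeled by the quadrant rule — tail (PC1 < 0, PC2 ≥ 0),
sac (PC1 ≥ 0, PC2 ≥ 0), duct (PC2 < 0) — after anchoring the axes so tail
samples score negative on PC1 and duct samples negative on PC2. The rule
presumes a specific geometry: the tail–sac contrast along PC1 and the duct
contrast pointing down PC2. The synthetic bulk design was calibrated so
this geometry holds (see below); on real data the sample score plot
(`attr(gene_set, "scores")`) should be inspected before trusting the labels.

PLS-DA is a two-component NIPALS PLS2 fit on the one-hot class matrix,
with `Q² = 1 − PRESS/TSS` under stratified cross-validation (requested
7 folds, reduced with a warning to the smallest class size — five here).
The fit is cross-checked in the test suite against `mixOmics::plsda`.
Differential expression uses a two-sided Welch t-test on the transformed
values with BH adjustment, size-factor-normalized fold changes
(pseudocount 0.5), thresholds adjusted p < 0.001 and fold change > 4, and
a cap of 100 genes per part (ties broken by |log2FC|, then gene id). The
Welch-on-VST test is a deliberate stand-in for a negative-binomial Wald
test: the filter's behavior is threshold-driven, and the t-test keeps the
stage dependency-light and exactly reproducible.

## Single cell

QC removes cells with fewer than 300 expressed genes and/or fewer than 500
transcripts, then drops samples not retaining strictly more than 500 cells;
all boundaries are strict as worded, so a cell at exactly (300, 500) is
kept. Normalization computes Pearson residuals under a negative-binomial
null with per-gene mean `mu = depth_cell × gene_rate` and a fixed size
θ = 100, clipped to ±√(n_cells). A fixed θ replaces regularized per-gene
dispersion estimation; for marker detection and clustering on well-separated
synthetic types, the residual scale, not the exact θ, is what matters.

Clustering is k-means on the top 30 principal components (10 restarts,
seeded); `k = "auto"` selects k ∈ [4, 16] by maximum mean silhouette width.
k-means was chosen because it is deterministic given a seed and adequate
for well-separated types; graph-based clustering would be needed for
continuous differentiation trajectories, which the generator does not
emulate. Markers come from one-vs-rest Wilcoxon rank-sum tests (normal
approximation with tie and continuity corrections, vectorized; verified
against `wilcox.test` to 1e-9), BH adjustment, and log2 fold changes of
depth-normalized means with pseudocount 1. Cluster-to-part assignment tests
the top ≤ 100 markers of each cluster for hypergeometric enrichment in each
part's gene list against the gene-set universe, BH across the three parts
within a cluster; the smallest adjusted p below 0.05 wins and exact ties
yield "none".

## Spatial

Zone-A cross-section regions are classed by perimeter: proximal below 500
pixels, distal above 1000, middle otherwise (boundaries inclusive to
middle, per the strict wording). Spots join the nearest same-zone,
same-section region centroid (ties to the lowest region id). Marker-set
trends are unweighted OLS of per-region mean depth-normalized expression on
region perimeter — a `weights` extension would be natural but region spot
counts are balanced by construction here. The hematoxylin–perimeter
correlation is a plain Pearson test.

Deconvolution regresses depth-normalized spot expression (scaled to the
median spot depth) on cell-type signatures under nonnegativity
(`pracma::lsqnonneg`) and renormalizes coefficients to sum to one. This
replaces a conditional-autoregressive spatial prior; spots are treated as
independent, which is the right baseline for a generator without spatial
autocorrelation of cell-type mixtures beyond the region structure. The
signature gene filter keeps genes with best per-cluster average log2 fold
change strictly above 2, at least 200 spatial counts, and detection in at
least 50 spots.

## Proteomics and layers

Percent of total spectra, NSAF (`(SpC/L)/Σ(SpC/L)`), and iBAQ
(intensity divided by the number of fully tryptic peptides of 6–30
residues, cleaving after K/R except before P) are computed per sample.
The silk-protein filter requires: (i) nonzero spectra in ≥ 1 gland
replicate; (ii) nonzero spectra in ≥ 2 distinct solvents; (iii) a predicted
signal peptide; (iv) mean percent of total spectra across all fiber
identification samples (zeros included) strictly greater than 0.15. The
mean in (iv) is unweighted over the nine solvent × replicate samples.

Layer inference recomputes relative abundances over the identified proteins
only, then tests 2 M against 8 M urea per protein with a two-sided Welch
t-test and BH adjustment across the tested proteins (the adjustment can be
disabled for literal replication of an unadjusted analysis). Significant
and higher at 2 M ⇒ enriched-2M; at 8 M ⇒ enriched-8M; otherwise a strictly
maximal 4 M mean (configurable margin, default 0) ⇒ peak-4M. The
zone-to-layer map is A→core, B→middle, C→outer, and `consistency` records
whether the urea class agrees (8M↔core, 4M-peak↔middle, 2M↔outer). The
intact-vs-dissolved control contributes correlation structure (average
linkage on 1 − r; Newick export via `ape`) and per-protein 2 M contrasts,
but never changes a layer assignment — removing it leaves the model
untouched, which the tests assert indirectly by building the model from the
intact series alone. Lumen-layer H&E objects are matched to zones by
nearest vesicle centroid after joint standardization, with majority vote
per layer and ties left unmapped.

## The synthetic gland: what it emulates, and what it does not

`make_design()` freezes the study conditions:

* 2,000 genes; eight cell types (three in zone A, one each in B and C, one
  shared, two duct); 22–25 markers per zone type, 10 for the shared type,
  8 per duct type; marker effect log2 = 3 in the producing type.
* Five bulk replicates per tissue at NB dispersion 0.1 (size 10); 3,000
  cells over four animals at size 2; six sections × 150 spots at size 5;
  11 tail regions with perimeters 250–1480 px.
* 18 fiber proteins (8 core, 2 middle, 8 outer) with logistic urea
  extractability — midpoints 1.5 M (outer), 3.5 M (middle), 6.0 M (core),
  slope 0.7 M — chosen so a 2 M extract is outer-dominated, a 4 M extract
  shows the middle peak, and an 8 M extract approaches the dissolved-fiber
  composition. 200 contaminant proteins each violate exactly one filter
  criterion. Spectral counts are multinomial with a fixed total of 10,000
  per sample, so totals are conserved exactly; biological replicate
  variability enters as a lognormal abundance jitter (sdlog 0.15).
* H&E means per zone (A hematoxylin-rich, C eosin-rich, sd 12), with a
  zone-A hematoxylin gradient against perimeter whose coefficient (−6 per
  perimeter SD) implies a population correlation near −0.45.

Two structural choices deserve explanation, because they were forced by the
analysis rather than free:

**Gland-program background.** Planted part-specific genes are expressed
throughout the gland (background 2^0.8 in every gland cell type) and rise
8-fold in their own type, and body tissue contains 40% dilute gland. The
two sign-filter steps require every true gene to be simultaneously higher
in body than head (step 1) and higher in pooled gland than body (step 2).
At dispersion 0.1 with five replicates, a gene private to one gland part
cannot carry both margins — the two requirements bound the needed pooled
expression above what a single part can supply — so a generator with
gland-sparse markers makes the published filter structurally unable to
recover them. Real silk genes are in fact among the most highly expressed
genes of the gland, and the filter classifies genes by *relative* part
preference; the generator follows that regime, including silk-scale
baselines for the gland program genes (lognormal, median 30 versus 5).

**Middle-layer membership.** The AmSp-like proteins are placed in zone C /
outer layer with abundance 0.5 each (about 1% of the fiber), and the middle
layer is MaSp3a/b. With the 2-vs-8 M test at α = 0.05, each truly balanced
middle protein still has a ~5% false-positive chance per seed; the
probability that *all* middle proteins stay non-significant scales as
0.95^k, so the middle class is kept small and dominated by the two
strongly 4 M-peaked proteins.

Not emulated: read- or UMI-level noise, batch effects between animals,
ambient RNA, doublets, spatial autocorrelation beyond region structure,
peptide-level MS effects (shared peptides, missed cleavages, modified
residues), or image content. Passing tests therefore demonstrate that the
implementations perform their stated computations and that the inference
chain is coherent under overdispersed count noise — not that the pipeline
is robust to batch or protein-inference artifacts in real data.

## Numerical choices and degenerate inputs

* Sign filters use strictly positive loadings; a zero-variance gene loads 0
  and is dropped.
* PCA/PLS axis signs are anchored to named tissues; degenerate (zero
  variance) PCA raises an error.
* Zero-depth units, all-zero matrices, missing lengths/intensities, missing
  molarity series, and zero-total MS samples raise errors naming the unit.
* Welch tests with two constant equal groups return p = 1 (p = 0 when means
  differ with zero variance); rank-sum p-values use tie-corrected normal
  approximation with continuity correction.
* Ties: DE ranking (adjusted p, |log2FC|, gene id), spot-region assignment
  (lowest region id), part assignment and histology votes (ties ⇒ none /
  unmapped), deconvolution all-zero solutions (uniform, flagged).
* One RNG stream per assay is derived from the master seed, so each assay
  can be regenerated independently and every result is reproducible from a
  single integer.

## Problem sizes in the test suite

The suite exercises full-scale defaults where the statistics demand it
(gene-set recovery, spatial trends, layer recovery, deconvolution) and
reduced scales elsewhere (300–1,200 cells, 40–120 spots) as the package's
chosen desk-scale echo of the study dimensions; all scales are ordinary
function arguments, not hidden constants.

## Known limitations

* The distance cutoff of the gene-set step is convention-bound; transferring
  it to data processed with another transform requires recalibration.
* The quadrant labeling rule assumes the tail–sac–duct triangle geometry
  described above; heavily unbalanced designs can rotate PC1/PC2 and
  scramble the labels even when distances are informative.
* NNLS deconvolution ignores spatial smoothing and cell-size differences
  between types.
* The layer model treats zones and layers as one-to-one; proteins secreted
  by several zones receive their layer from the urea class alone and are
  flagged inconsistent rather than modeled as mixtures.
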