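# ampulla

Multi-omics mapping of silk gland zones and fiber layer architecture.

Orb-weaving spiders spin their strongest silk, the major ampullate (dragline)
fiber, from a gland with three anatomical parts — tail, sac, and duct — whose
tail/sac epithelium is partitioned into three secretory zones (A, B, C). The
secretions of these zones assemble into concentric fiber layers: zone A forms
the core, zone B a middle layer, zone C the thin outer layer. `ampulla`
implements, as reusable R functions, the inference chain that connects the
omics readouts of this system and assigns each silk protein to its producing
cell type, glandular zone, and fiber layer:

* **Gland gene set (bulk RNA-seq).** TPM prefilter (TPM > 4 in ≥ 1 sample);
  two sign-oriented PCA retention steps (head vs body, gland vs body, with a
  rescue list for curated silk genes); a PCA loading-distance step on
  tail/sac/duct samples with the quadrant rule
  tail (PC1 < 0, PC2 ≥ 0), sac (PC1 ≥ 0, PC2 ≥ 0), duct (PC2 < 0);
  two-component PLS-DA with cross-validated predictive relevance
  *Q²* = 1 − PRESS/TSS; and stringent one-vs-rest differential expression
  (adjusted *p* < 0.001, fold change > 4, ≤ 100 genes per part).
* **Single cell.** QC (≥ 300 genes, ≥ 500 transcripts per cell; > 500 cells
  per sample), negative-binomial Pearson-residual normalization, k-means
  clustering on top principal components with silhouette-based model
  selection, one-vs-rest Wilcoxon marker calling, and hypergeometric
  assignment of clusters to gland parts via gene-set overlap.
* **Spatial.** Perimeter-based proximo-distal ordering of zone A
  (< 500 px proximal, > 1000 px distal), nearest-centroid spot-to-region
  assignment, marker-set expression trends against cross-section perimeter,
  hematoxylin–perimeter correlation, signature-based spot deconvolution by
  nonnegative least squares with sum-to-one renormalization, and per-class
  mean cell-type proportions.
* **Proteomics.** Percent of total spectra, NSAF, and iBAQ quantification;
  the four-criteria silk-protein filter (present in the gland, found in ≥ 2
  solvents, signal peptide, mean percent of total spectra > 0.15).
* **Layer inference.** Restricted-set relative abundances across a 2/4/8 M
  urea series, Welch tests of 2 M vs 8 M enrichment with BH adjustment
  (enriched-2M / peak-4M / enriched-8M classes), the intact-vs-dissolved
  solubility control, vesicle–lumen H&E matching, and the final
  zone-to-layer model (A→core, B→middle, C→outer) with a consistency flag.

A first-class synthetic data generator (`make_design()`,
`simulate_transcriptomes()`, `simulate_proteomics()`,
`simulate_histology()`) emulates the whole study — eight cell types with
marker programs, negative-binomial counts for bulk/cells/spots, a tapering
tail with increasing cross-section perimeters, a three-layer fiber with
logistic urea extractability per layer, and zone-coded histology — with a
known ground truth, so every stage is testable without any external data.

## Worked example

```r
library(ampulla)

d <- make_design()
d
#> <gland_design> 2000 genes, 8 cell types, 11 tail regions, 18 fiber proteins + 200 contaminants

spectra <- simulate_proteomics(d, seed = 1)
gland <- subset_spectra(spectra, samples = spectra$meta$source == "gland")
flags <- setNames(spectra$protein_meta$signal_peptide,
                  spectra$protein_meta$protein)
id <- identify_silk_proteins(gland, fiber_id_samples(spectra), flags)
length(attr(id, "silk"))
#> [1] 18

prof <- relative_urea_profiles(urea_series(spectra, "intact"), attr(id, "silk"))
uc <- urea_enrichment_test(prof)
zoo <- setNames(d$protein_table$zone, d$protein_table$protein)
model <- build_layer_model(zoo, uc)
head(model[, c("protein", "zone_of_origin", "urea_class", "layer", "consistency")], 4)
#>   protein zone_of_origin  urea_class layer consistency
#> 1  MaSp1a              A enriched-8M  core        TRUE
#> 2  MaSp1b              A enriched-8M  core        TRUE
#> 3  MaSp1c              A enriched-8M  core        TRUE
#> 4  MaSp2b              A enriched-8M  core        TRUE
table(model$layer)
#>   core middle  outer
#>      8      2      8
```

The four-criteria filter recovers exactly the 18 planted fiber proteins out
of 218 candidates, and the urea-gradient analysis places 17 of the 18 on
their true layer with a consistent enrichment class in this run (the
zone-A spidroins enriched at 8 M, MaSp3a/b peaking at 4 M, and the SpiCE /
AmSp-like proteins enriched at 2 M).

The full pipeline — gene set, single cell, spatial, proteomics, layers — runs
from a serialized bundle:

```r
bundle <- simulate_bundle(seed = 1, dir = "bundle")
res <- run_pipeline(bundle, outdir = "results")   # writes TSV/CSV/JSON tables
res$layers$model
```

A thin command-line wrapper with `simulate` and `run-all` subcommands is
installed under `inst/cli/ampulla.R`.

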