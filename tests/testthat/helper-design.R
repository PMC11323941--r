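# Shared fixtures: reduced-scale designs and small utilities used across the
# test files. Everything is generated in code at test time.

small_design <- function(...) {
  make_design(modifyList(list(n_cells = 600L, n_sc_samples = 2L), list(...)))
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  (sij - expct) / ((si + sj) / 2 - expct)
}

# Run the four-step gene-set filter on a simulated bundle.
run_geneset_filter <- function(sim, cutoff = 0.33, rescue = character()) {
  counts <- tpm_prefilter(sim$bulk)
  vst <- vst_counts(counts)
  s1 <- pca_sign_filter(vst, groups = list("head", "body"), gland_side = 2)
  s2 <- pca_sign_filter(subset_expr(vst, genes = s1),
                        groups = list(c("tail", "sac", "duct"), "body"),
                        gland_side = 1, rescue = rescue)
  gland_units <- vst$meta$unit[vst$meta$tissue %in% c("tail", "sac", "duct")]
  vst2 <- subset_expr(vst, genes = s2, units = gland_units)
  list(gene_set = gland_gene_set(vst2, cutoff = cutoff), vst = vst2,
       steps = list(s1 = s1, s2 = s2), counts = counts)
}

# A tiny expression matrix with tissue metadata, built by hand.
toy_expr <- function(values, tissue, lengths = NULL) {
  colnames(values) <- sprintf("%s_%d", tissue, ave(seq_along(tissue),
                                                   tissue, FUN = seq_along))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (!is.null(lengths)) names(lengths) <- rownames(values)
  expr_matrix(values, "counts",
              meta = data.frame(unit = colnames(values), tissue = tissue),
              gene_lengths = lengths)
}

# Spectra table built from a plain count matrix and minimal metadata.
toy_spectra <- function(counts, solvent = rep("urea", ncol(counts)),
                        molarity = rep(NA_real_, ncol(counts)),
                        preparation = rep("none", ncol(counts)),
                        source = rep("fiber", ncol(counts)),
                        lengths = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%02d", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- setNames(rep(100, nrow(counts)),
                                            rownames(counts))
  spectra_table(counts,
                data.frame(sample_id = colnames(counts), source = source,
                           solvent = solvent, molarity = molarity,
                           preparation = preparation,
                           replicate = seq_len(ncol(counts))),
                lengths)
}
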