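#' Simulate spectral-count proteomics of gland and fiber
#'
#' Generates a [spectra_table()] covering: three gland replicates; fiber
#' extracts in three solvents (HFIP, LiBr, urea; three replicates each) used
#' for silk-protein identification; a urea molarity series (2, 4, 8 M) on
#' intact fibers, where protein extractability is logistic in molarity with a
#' layer-dependent midpoint; and the same series on fibers first dissolved in
#' formic acid, where extractability is layer-independent. Counts in each
#' sample are multinomial over proteins with a fixed total, so sampling
#' conserves the configured spectra per sample exactly. Replicate-to-replicate
#' biological variability enters as a lognormal jitter on protein abundances.
#'
#' Contaminant proteins are planted in four classes, each violating exactly
#' one criterion of the silk-protein filter: `no_gland` (absent from gland),
#' `one_solvent` (extracted by a single solvent), `no_signal` (no signal
#' peptide), and `low_abundance` (mean percent of total spectra below the
#' threshold).
#'
#' @param design a [make_design()] object.
#' @param seed integer seed.
#' @return A `spectra_table`.
#' @export
simulate_proteomics <- function(design, seed) {
  stopifnot(inherits(design, "gland_design"))
  d <- design
  set.seed(derive_assay_seed(seed, "proteomics"))
  if (d$total_spectra <= 0) .stopf("total spectra per sample must be positive")

  pt <- d$protein_table
  con <- contaminant_table(d)
  proteins <- c(pt$protein, con$protein)
  lengths <- stats::setNames(c(pt$length, con$length), proteins)
  signal <- stats::setNames(c(pt$signal_peptide, con$signal_peptide), proteins)

  samples <- proteomics_sample_sheet(d)
  counts <- matrix(0L, length(proteins), nrow(samples),
                   dimnames = list(proteins, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    w <- sample_weights(d, pt, con, samples[i, ])
    w <- w * stats::rlnorm(length(w), 0, d$ms_rep_sdlog)
    counts[, i] <- stats::rmultinom(1, d$total_spectra, prob = w)[, 1]
  }
  intensity <- counts * stats::rlnorm(length(counts), log(1e5), 0.2)

  spectra_table(counts, samples, lengths, intensity = intensity,
                protein_meta = data.frame(
                  protein = proteins,
                  signal_peptide = unname(signal),
                  is_silk = proteins %in% pt$protein,
                  truth = c(pt$layer, con$class)))
}

contaminant_table <- function(d) {
  n <- d$contaminants
  cls <- rep(names(n), n)
  k <- length(cls)
  if (!k) return(data.frame(protein = character(), length = numeric(),
                            signal_peptide = logical(), class = character(),
                            abundance = numeric()))
  data.frame(
    protein = sprintf("CON_%03d", seq_len(k)),
    length = round(seq(200, 800, length.out = k)),
    signal_peptide = cls != "no_signal",
    class = cls,
    abundance = c(no_gland = 0.8, one_solvent = 2.0, no_signal = 0.8,
                  low_abundance = 0.05)[cls],
    stringsAsFactors = FALSE)
}

proteomics_sample_sheet <- function(d) {
  reps <- seq_len(d$n_ms_reps)
  rbind(
    data.frame(sample_id = sprintf("gland_%d", reps), source = "gland",
               solvent = "none", molarity = NA_real_, preparation = "none",
               replicate = reps),
    do.call(rbind, lapply(d$fiber_solvents, function(s)
      data.frame(sample_id = sprintf("fiber_%s_%d", s, reps), source = "fiber",
                 solvent = s, molarity = NA_real_, preparation = "none",
                 replicate = reps))),
    do.call(rbind, lapply(d$urea_molarities, function(m)
      data.frame(sample_id = sprintf("intact_%gM_%d", m, reps), source = "fiber",
                 solvent = "urea", molarity = m, preparation = "intact",
                 replicate = reps))),
    do.call(rbind, lapply(d$urea_molarities, function(m)
      data.frame(sample_id = sprintf("dissolved_%gM_%d", m, reps),
                 source = "fiber", solvent = "urea", molarity = m,
                 preparation = "dissolved", replicate = reps))))
}

# Expected (pre-jitter) abundance weight of every protein in one MS sample.
sample_weights <- function(d, pt, con, s) {
  silk <- pt$abundance
  if (s$source == "gland") {
    w_con <- ifelse(con$class == "no_gland", 0, 0.5)
  } else if (s$preparation == "intact") {
    silk <- silk * stats::plogis((s$molarity - pt$midpoint) / pt$slope)
    w_con <- ifelse(con$class == "one_solvent", 0, con$abundance)
  } else if (s$preparation == "dissolved") {
    # formic-acid pre-dissolution removes the layer structure entirely
    w_con <- ifelse(con$class == "one_solvent", 0, con$abundance)
  } else {
    # identification extract: the solvent fully dissolves the fiber
    w_con <- ifelse(con$class == "one_solvent" & s$solvent != "HFIP",
                    0, con$abundance)
  }
  c(silk, w_con)
}
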