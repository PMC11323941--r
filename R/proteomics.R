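#' Percentage of total spectra
#'
#' Each protein's spectral counts as a percentage of the total spectra of
#' its sample; proteins absent from a sample are 0. Columns sum to 100.
#'
#' @param table a [spectra_table()].
#' @return proteins x samples percentage matrix.
#' @export
percent_total_spectra <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0))
    .stopf("zero-total sample(s): %s",
           paste(colnames(table$counts)[totals == 0], collapse = ", "))
  sweep(table$counts, 2, totals, "/") * 100
}

#' Normalized spectral abundance factor (NSAF)
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)` per sample, with protein
#' lengths `L` in amino acids. Columns sum to 1.
#'
#' @param table a [spectra_table()] with lengths.
#' @return proteins x samples NSAF matrix.
#' @export
nsaf <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(table$lengths) || anyNA(table$lengths))
    .stopf("protein lengths are required for NSAF")
  saf <- table$counts / table$lengths
  denom <- colSums(saf)
  if (any(denom == 0))
    .stopf("zero-total sample(s): %s",
           paste(colnames(table$counts)[denom == 0], collapse = ", "))
  sweep(saf, 2, denom, "/")
}

# Fully tryptic peptides: cleave after K or R except when followed by P.
.tryptic_peptides <- function(seq) {
  cuts <- gregexpr("(?<=[KR])(?!P)", seq, perl = TRUE)[[1]]
  cuts <- cuts[cuts != -1 & cuts <= nchar(seq)]
  starts <- c(1L, as.integer(cuts))
  ends <- c(starts[-1] - 1L, nchar(seq))
  substring(seq, starts, ends)
}

#' Intensity-based absolute quantification (iBAQ)
#'
#' `iBAQ_i = intensity_i / n_i`, where `n_i` is the number of theoretical
#' fully tryptic peptides of protein i (cleavage after K or R except before
#' P) with length between `pep_min` and `pep_max` residues. Proteins with
#' no qualifying peptide are excluded (NA) and flagged.
#'
#' @param table a [spectra_table()] carrying intensities.
#' @param sequences named character vector of protein sequences.
#' @param pep_min,pep_max peptide length window (default 6-30 aa).
#' @return proteins x samples iBAQ matrix; attribute `flagged` lists
#'   proteins without qualifying peptides.
#' @export
ibaq <- function(table, sequences, pep_min = 6, pep_max = 30) {
  stopifnot(inherits(table, "spectra_table"))
  if (is.null(table$intensity)) .stopf("intensities are required for iBAQ")
  prot <- rownames(table$counts)
  sequences <- sequences[prot]
  if (anyNA(sequences)) .stopf("missing sequence(s) for: %s",
                               paste(prot[is.na(sequences)], collapse = ", "))
  npep <- vapply(sequences, function(s) {
    len <- nchar(.tryptic_peptides(s))
    sum(len >= pep_min & len <= pep_max)
  }, numeric(1))
  out <- table$intensity / npep
  out[npep == 0, ] <- NA_real_
  attr(out, "flagged") <- prot[npep == 0]
  out
}

#' Identify fiber-constituent silk proteins (four-criteria filter)
#'
#' A protein qualifies when it (i) is present (nonzero spectra) in at least
#' one gland replicate, (ii) is found in at least two distinct fiber
#' solvents, (iii) carries a predicted signal peptide, and (iv) has a mean
#' percentage of total spectra across all fiber replicates (all solvents
#' pooled, zeros included) strictly greater than `threshold`.
#'
#' @param gland `spectra_table` of gland replicates.
#' @param fiber `spectra_table` of the fiber identification extracts
#'   (the three solvents).
#' @param flags named logical vector: signal peptide predicted.
#' @param threshold mean percent-total-spectra cutoff (default 0.15).
#' @return data.frame with per-criterion booleans, the mean percentage, and
#'   a `silk` column; attribute `silk` holds the passing protein ids.
#' @export
identify_silk_proteins <- function(gland, fiber, flags, threshold = 0.15) {
  stopifnot(inherits(gland, "spectra_table"), inherits(fiber, "spectra_table"))
  if (anyNA(fiber$meta$solvent) || any(fiber$meta$solvent == "none"))
    .stopf("fiber samples must carry solvent metadata")
  if (length(unique(fiber$meta$solvent)) < 2)
    .stopf("fiber table must contain at least two solvents")
  prot <- rownames(fiber$counts)
  gl <- rowSums(gland$counts > 0) > 0
  in_gland <- stats::setNames(rep(FALSE, length(prot)), prot)
  common <- intersect(prot, names(gl))
  in_gland[common] <- gl[common]
  solvents <- unique(fiber$meta$solvent)
  n_solv <- rowSums(vapply(solvents, function(s)
    rowSums(fiber$counts[, fiber$meta$solvent == s, drop = FALSE] > 0) > 0,
    logical(length(prot))))
  pct <- percent_total_spectra(fiber)
  mean_pct <- rowMeans(pct)
  sp <- flags[prot]
  sp[is.na(sp)] <- FALSE
  res <- data.frame(
    protein = prot,
    in_gland = unname(in_gland),
    n_solvents = unname(n_solv),
    two_solvents = unname(n_solv >= 2),
    signal_peptide = unname(sp),
    mean_pct = unname(mean_pct),
    above_threshold = unname(mean_pct > threshold), row.names = NULL)
  res$silk <- res$in_gland & res$two_solvents & res$signal_peptide &
    res$above_threshold
  attr(res, "silk") <- res$protein[res$silk]
  res
}
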