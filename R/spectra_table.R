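#' Spectral-count table with MS sample metadata
#'
#' Container for a proteins x samples matrix of spectral counts, optional
#' summed intensities, per-protein lengths, and per-sample metadata
#' (source gland/fiber, solvent, urea molarity, preparation intact/dissolved,
#' replicate).
#'
#' @param counts integer matrix, proteins x samples, with dimnames.
#' @param meta data.frame with columns `sample_id`, `source`, `solvent`,
#'   `molarity`, `preparation`, `replicate`.
#' @param lengths named numeric vector of protein lengths (aa).
#' @param intensity optional numeric matrix matching `counts`.
#' @param protein_meta optional data.frame of per-protein annotations.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(counts, meta, lengths, intensity = NULL,
                          protein_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    .stopf("spectral counts must be nonnegative integers")
  need <- c("sample_id", "source", "solvent", "molarity", "preparation",
            "replicate")
  if (!all(need %in% names(meta)))
    .stopf("sample metadata must contain: %s", paste(need, collapse = ", "))
  if (!identical(as.character(meta$sample_id), colnames(counts)))
    .stopf("meta$sample_id must match count matrix columns")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    .stopf("positive protein lengths are required for every protein")
  if (!is.null(intensity) && !identical(dim(intensity), dim(counts)))
    .stopf("intensity matrix must match the count matrix")
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, lengths = lengths,
                 intensity = intensity, protein_meta = protein_meta),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d proteins x %d MS samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$source), collapse = "/")))
  invisible(x)
}

#' Subset a spectra table by samples and/or proteins
#'
#' @param x a `spectra_table`.
#' @param samples character vector of sample ids, or a logical over samples.
#' @param proteins character vector of protein ids.
#' @return A `spectra_table`.
#' @export
subset_spectra <- function(x, samples = NULL, proteins = NULL) {
  stopifnot(inherits(x, "spectra_table"))
  keep_s <- colnames(x$counts)
  if (!is.null(samples))
    keep_s <- if (is.logical(samples)) keep_s[samples] else samples
  keep_p <- if (is.null(proteins)) rownames(x$counts) else proteins
  spectra_table(x$counts[keep_p, keep_s, drop = FALSE],
                x$meta[match(keep_s, x$meta$sample_id), , drop = FALSE],
                x$lengths[keep_p],
                intensity = if (is.null(x$intensity)) NULL else
                  x$intensity[keep_p, keep_s, drop = FALSE],
                protein_meta = if (is.null(x$protein_meta)) NULL else
                  x$protein_meta[match(keep_p, x$protein_meta$protein), ,
                                 drop = FALSE])
}

#' Fiber identification extracts (one sample per solvent and replicate)
#'
#' @param x a `spectra_table` from [simulate_proteomics()] or disk.
#' @return `spectra_table` restricted to the fiber solvent extracts.
#' @export
fiber_id_samples <- function(x) {
  stopifnot(inherits(x, "spectra_table"))
  subset_spectra(x, samples = x$meta$source == "fiber" &
                   x$meta$preparation == "none")
}

#' Urea molarity series on intact or formic-acid-dissolved fibers
#'
#' @param x a `spectra_table`.
#' @param preparation `"intact"` or `"dissolved"`.
#' @return `spectra_table` restricted to the requested series.
#' @export
urea_series <- function(x, preparation = c("intact", "dissolved")) {
  preparation <- match.arg(preparation)
  subset_spectra(x, samples = x$meta$preparation == preparation &
                   !is.na(x$meta$molarity))
}
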