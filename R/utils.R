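# Internal helpers shared across modules.

# One RNG stream per assay, derived from (master seed, assay tag) so that
# assays can be regenerated independently of each other.
.assay_offsets <- c(bulk = 101L, cells = 211L, spatial = 307L,
                    proteomics = 401L, histology = 503L, pipeline = 601L,
                    sequences = 701L)

derive_assay_seed <- function(seed, assay) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required; refusing to simulate nondeterministically")
  assay <- match.arg(assay, names(.assay_offsets))
  (as.integer(seed) %% 1000003L) * 1009L + .assay_offsets[[assay]]
}

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Scale columns of a count matrix to a common depth (default: median depth).
depth_normalize <- function(x, target = NULL) {
  totals <- Matrix::colSums(x)
  if (any(totals <= 0)) .stopf("zero-depth unit(s): %s",
                               paste(colnames(x)[totals <= 0], collapse = ", "))
  if (is.null(target)) target <- stats::median(totals)
  sweep(as.matrix(x), 2, totals / target, "/")
}

# Median-of-ratios size factors over genes with a positive geometric mean.
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) .stopf("all-zero count matrix")
  loggeo <- rowMeans(log(counts))            # -Inf where any zero
  use <- is.finite(loggeo)
  if (!any(use)) .stopf("no gene has nonzero counts in every unit; cannot compute size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo[use]))
  })
  sf
}
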