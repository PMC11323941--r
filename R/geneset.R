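#' Transcripts per million
#'
#' Length-rate normalization: `TPM_g = 1e6 * (count_g/length_g) /
#' sum_j(count_j/length_j)` within each unit.
#'
#' @param counts an [expr_matrix()] on the counts layer with gene lengths.
#' @param lengths optional named length vector overriding the one stored in
#'   `counts`.
#' @return an `expr_matrix` on the TPM layer.
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  if (is.null(lengths)) lengths <- counts$gene_lengths
  if (is.null(lengths)) .stopf("gene lengths are required to compute TPM")
  lengths <- lengths[rownames(counts$values)]
  if (anyNA(lengths) || any(lengths <= 0)) .stopf("all gene lengths must be positive")
  rate <- as.matrix(counts$values) / lengths
  denom <- colSums(rate)
  if (any(denom == 0))
    .stopf("zero-depth unit(s): %s",
           paste(colnames(counts$values)[denom == 0], collapse = ", "))
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expr_matrix(tpm, "TPM", meta = counts$meta, gene_lengths = lengths)
}

#' Keep genes expressed above a TPM floor in at least one sample
#'
#' @param counts counts `expr_matrix` with gene lengths.
#' @param min_tpm TPM floor (default 4); a gene is kept when its TPM exceeds
#'   the floor in at least one sample.
#' @return counts `expr_matrix` restricted to the kept genes.
#' @export
tpm_prefilter <- function(counts, min_tpm = 4) {
  tpm <- compute_tpm(counts)
  keep <- rownames(tpm$values)[apply(tpm$values > min_tpm, 1, any)]
  subset_expr(counts, genes = keep)
}

#' Variance-flattening transform of counts
#'
#' Size factors by median-of-ratios over genes with a nonzero geometric
#' mean, then `log2(count/sizefactor + 1)`. This plays the
#' variance-stabilizing role in the gene-set filter.
#'
#' @param counts counts `expr_matrix` with at least 2 units.
#' @return an `expr_matrix` on the VST layer.
#' @export
vst_counts <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  if (ncol(counts$values) < 2) .stopf("at least 2 units are required")
  m <- as.matrix(counts$values)
  sf <- size_factors(m)
  v <- log2(sweep(m, 2, sf, "/") + 1)
  out <- expr_matrix(v, "VST", meta = counts$meta,
                     gene_lengths = counts$gene_lengths)
  attr(out, "size_factors") <- sf
  out
}

# PCA helper: samples as observations. Returns scores (samples x PC) and
# loadings scaled as cov(gene, unit-variance score), i.e. rotation * sdev,
# so a loading is read on the expression (log2) scale.
.pca_samples <- function(v) {
  p <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) .stopf("degenerate PCA: no variance across samples")
  list(scores = p$x, loadings = sweep(p$rotation, 2, p$sdev, "*"),
       sdev = p$sdev)
}

#' Sign-oriented PCA retention filter (gene-set steps 1 and 2)
#'
#' PCA on the samples of two tissue groups; PC1 is oriented so the
#' gland-side group has a positive mean score, and genes with a strictly
#' positive PC1 loading are retained. A rescue list can force-include genes
#' regardless of their loading sign (step 2 of the filter).
#'
#' @param vst VST `expr_matrix` whose metadata has a `tissue` column.
#' @param groups length-2 character vector of tissue labels, or a list of two
#'   character vectors of tissues to pool per side.
#' @param gland_side which element of `groups` is the gland-containing side
#'   (1 or 2); defaults to 2.
#' @param rescue character vector of gene ids to force-include.
#' @return character vector of retained gene ids.
#' @export
pca_sign_filter <- function(vst, groups, gland_side = 2L, rescue = character()) {
  stopifnot(inherits(vst, "expr_matrix"), vst$layer == "VST")
  if (!is.list(groups)) groups <- as.list(groups)
  stopifnot(length(groups) == 2)
  tis <- vst$meta$tissue
  side <- ifelse(tis %in% groups[[1]], 1L, ifelse(tis %in% groups[[2]], 2L, NA))
  units <- vst$meta$unit[!is.na(side)]
  side <- side[!is.na(side)]
  if (min(table(side)) < 2) .stopf("at least 2 samples per group are required")
  v <- as.matrix(vst$values)[, units, drop = FALSE]
  p <- .pca_samples(v)
  flip <- mean(p$scores[side == gland_side, 1]) < 0
  l1 <- if (flip) -p$loadings[, 1] else p$loadings[, 1]
  union(names(l1)[l1 > 0], intersect(rescue, rownames(v)))
}

#' Gland-specific gene set by loading distance (gene-set step 3)
#'
#' PCA on tail, sac, and duct samples; per-gene Euclidean distance of the
#' (PC1, PC2) loadings from the origin; genes beyond the cutoff are labeled
#' by the quadrant rule tail (PC1 < 0, PC2 >= 0), sac (PC1 >= 0, PC2 >= 0),
#' duct (PC2 < 0). Axes are oriented so tail samples score negative on PC1
#' and duct samples negative on PC2. Loadings are on the covariance scale
#' (gene-by-score covariance with unit-variance scores), so the distance is
#' read in log2 expression units; the default cutoff 0.33 corresponds to
#' about 1.26-fold of structured variation.
#'
#' @param vst VST `expr_matrix` restricted to genes surviving steps 1-2,
#'   with a `tissue` metadata column covering tail, sac, duct.
#' @param cutoff loading-distance cutoff (default 0.33).
#' @return data.frame with per-gene `pc1`, `pc2`, `dist`, and `part`
#'   (tail/sac/duct/none).
#' @export
gland_gene_set <- function(vst, cutoff = 0.33) {
  stopifnot(inherits(vst, "expr_matrix"), vst$layer == "VST")
  tis <- vst$meta$tissue
  parts <- c("tail", "sac", "duct")
  if (any(table(factor(tis[tis %in% parts], levels = parts)) < 2))
    .stopf("at least 2 replicates of tail, sac, and duct are required")
  units <- vst$meta$unit[tis %in% parts]
  tis <- tis[vst$meta$unit %in% units]
  v <- as.matrix(vst$values)[, units, drop = FALSE]
  p <- .pca_samples(v)
  s <- p$scores[, 1:2, drop = FALSE]
  l <- p$loadings[, 1:2, drop = FALSE]
  if (mean(s[tis == "tail", 1]) > 0) { s[, 1] <- -s[, 1]; l[, 1] <- -l[, 1] }
  if (mean(s[tis == "duct", 2]) > 0) { s[, 2] <- -s[, 2]; l[, 2] <- -l[, 2] }
  dist <- sqrt(l[, 1]^2 + l[, 2]^2)
  part <- ifelse(dist <= cutoff, "none",
          ifelse(l[, 2] < 0, "duct",
          ifelse(l[, 1] < 0, "tail", "sac")))
  out <- data.frame(gene = rownames(v), pc1 = l[, 1], pc2 = l[, 2],
                    dist = dist, part = part, row.names = NULL)
  attr(out, "scores") <- s
  attr(out, "cutoff") <- cutoff
  out
}

#' Differential expression with stringent thresholds (one part vs the rest)
#'
#' One-vs-rest contrast of one gland part against the other two:
#' size-factor-normalized fold change, per-gene two-sided Welch t-test on
#' VST values, Benjamini-Hochberg adjustment; genes are retained when the
#' adjusted p-value is below `alpha` and the fold change exceeds `min_fc`,
#' and at most `cap` genes are returned, ranked by adjusted p (ties by
#' decreasing absolute log2 fold change, then gene id).
#'
#' @param counts counts `expr_matrix` of tail/sac/duct samples.
#' @param part the part tested against the other two.
#' @param alpha adjusted-p threshold (default 0.001).
#' @param min_fc fold-change threshold (default 4).
#' @param cap maximum genes returned (default 100).
#' @return data.frame `gene`, `log2fc`, `p`, `padj`, ordered by rank.
#' @export
differential_expression <- function(counts, part, alpha = 0.001, min_fc = 4,
                                    cap = 100) {
  stopifnot(inherits(counts, "expr_matrix"), counts$layer == "counts")
  tis <- counts$meta$tissue
  keep <- tis %in% c("tail", "sac", "duct")
  counts <- subset_expr(counts, units = counts$meta$unit[keep])
  tis <- counts$meta$tissue
  if (!part %in% tis) .stopf("part '%s' not among the samples", part)
  in_part <- tis == part
  if (sum(in_part) < 2 || sum(!in_part) < 2)
    .stopf("at least 2 replicates on each side of the contrast are required")
  m <- as.matrix(counts$values)
  norm <- sweep(m, 2, size_factors(m), "/")
  fc <- (rowMeans(norm[, in_part, drop = FALSE]) + 0.5) /
        (rowMeans(norm[, !in_part, drop = FALSE]) + 0.5)
  vst <- vst_counts(counts)
  v <- as.matrix(vst$values)
  p <- apply(v, 1, function(x) {
    a <- x[in_part]; b <- x[!in_part]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else stats::t.test(a, b)$p.value
  })
  padj <- stats::p.adjust(p, "BH")
  res <- data.frame(gene = rownames(m), log2fc = log2(fc), p = p, padj = padj,
                    row.names = NULL)
  res <- res[res$padj < alpha & fc > min_fc, , drop = FALSE]
  res <- res[order(res$padj, -abs(res$log2fc), res$gene), , drop = FALSE]
  utils::head(res, cap)
}

#' F1 score of a recovered gene set against planted part labels
#'
#' Primary metric: set-membership F1 — a gene counts as a true positive when
#' it enters the final gland-specific gene set and carries a planted part
#' label (tail/sac/duct). Alongside, `label_accuracy` reports the fraction
#' of those true positives whose assigned part equals the planted part, and
#' `f1_label` the stricter micro-F1 that additionally requires the labels to
#' match.
#'
#' @param geneset data.frame from [gland_gene_set()] (columns gene, part).
#' @param truth named character vector of planted part labels.
#' @return list with `precision`, `recall`, `f1` (membership),
#'   `label_accuracy`, and `f1_label`.
#' @export
geneset_f1 <- function(geneset, truth) {
  pred <- stats::setNames(rep("none", length(truth)), names(truth))
  pred[geneset$gene] <- geneset$part
  truth <- truth[names(pred)]
  in_set <- pred != "none"
  pos <- truth != "none"
  f1_of <- function(tp, fp, fn) {
    precision <- if (tp + fp) tp / (tp + fp) else 0
    recall <- if (tp + fn) tp / (tp + fn) else 0
    c(precision = precision, recall = recall,
      f1 = if (precision + recall) 2 * precision * recall / (precision + recall)
           else 0)
  }
  memb <- f1_of(sum(in_set & pos), sum(in_set & !pos), sum(pos & !in_set))
  lab <- f1_of(sum(in_set & pos & pred == truth),
               sum(in_set & !(pos & pred == truth)),
               sum(pos & pred != truth))
  tp_memb <- sum(in_set & pos)
  list(precision = unname(memb["precision"]), recall = unname(memb["recall"]),
       f1 = unname(memb["f1"]),
       label_accuracy = if (tp_memb) sum(in_set & pos & pred == truth) / tp_memb
                        else NA_real_,
       f1_label = unname(lab["f1"]))
}
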