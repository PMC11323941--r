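#' Quality-control filter for single cells
#'
#' Removes cells with fewer than `min_genes` expressed genes and/or fewer
#' than `min_counts` total transcripts (strict inequalities: a cell at
#' exactly the boundary is kept), then drops whole samples not retaining
#' more than `min_cells_per_sample` cells.
#'
#' @param cells counts `expr_matrix`; metadata may carry a `sample` column.
#' @param min_genes minimum expressed genes (default 300).
#' @param min_counts minimum total transcripts (default 500).
#' @param min_cells_per_sample a sample is kept only when strictly more than
#'   this many of its cells survive (default 500).
#' @return list with `cells` (filtered `expr_matrix`) and `cell_table`
#'   (per-cell QC data.frame).
#' @export
qc_filter <- function(cells, min_genes = 300, min_counts = 500,
                      min_cells_per_sample = 500) {
  stopifnot(inherits(cells, "expr_matrix"), cells$layer == "counts")
  v <- cells$values
  n_genes <- Matrix::colSums(v > 0)
  total <- Matrix::colSums(v)
  keep <- n_genes >= min_genes & total >= min_counts
  sample_id <- if ("sample" %in% names(cells$meta)) cells$meta$sample
               else rep("sample_1", ncol(v))
  kept_per_sample <- tapply(keep, sample_id, sum)
  good_samples <- names(kept_per_sample)[kept_per_sample > min_cells_per_sample]
  keep <- keep & sample_id %in% good_samples
  if (!any(keep)) .stopf("QC removed every cell")
  tab <- data.frame(cell = colnames(v), sample = sample_id,
                    n_genes_detected = as.integer(n_genes),
                    total_counts = as.numeric(total), kept = keep)
  list(cells = subset_expr(cells, units = colnames(v)[keep]), cell_table = tab)
}

#' Pearson-residual normalization of single-cell counts
#'
#' Residuals under a negative-binomial null with per-gene mean
#' `mu = depth_cell * gene_rate` and fixed size `theta`:
#' `r = (x - mu) / sqrt(mu + mu^2/theta)`, clipped to +/- sqrt(n_cells).
#'
#' @param cells post-QC counts `expr_matrix`.
#' @param theta fixed NB size for the null (default 100).
#' @return `expr_matrix` on the normalized layer (dense residual matrix).
#' @export
normalize_cells <- function(cells, theta = 100) {
  stopifnot(inherits(cells, "expr_matrix"), cells$layer == "counts")
  m <- as.matrix(cells$values)
  depth <- colSums(m)
  rate <- rowSums(m) / sum(m)
  mu <- outer(rate, depth)
  r <- (m - mu) / sqrt(mu + mu^2 / theta)
  r[!is.finite(r)] <- 0
  clip <- sqrt(ncol(m))
  r <- pmin(pmax(r, -clip), clip)
  expr_matrix(r, "normalized", meta = cells$meta)
}

#' Cluster cells by k-means on top principal components
#'
#' @param cells normalized `expr_matrix`.
#' @param k number of clusters, or `"auto"` to select k in `k_range` by
#'   maximum mean silhouette width.
#' @param n_pcs number of principal components (default 30).
#' @param seed integer seed (required; clustering must be reproducible).
#' @param k_range candidate k values for `"auto"` (default 4:16).
#' @return integer vector of cluster labels (contiguous from 0), named by
#'   cell; the chosen k is attached as attribute `k`.
#' @export
cluster_cells <- function(cells, k = "auto", n_pcs = 30, seed,
                          k_range = 4:16) {
  stopifnot(inherits(cells, "expr_matrix"))
  if (missing(seed)) stop("a seed is required for clustering")
  v <- as.matrix(cells$values)
  n <- ncol(v)
  n_pcs <- min(n_pcs, n - 1L, nrow(v))
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  run_km <- function(kk) {
    set.seed(seed)
    stats::kmeans(pc, centers = kk, nstart = 10, iter.max = 100)
  }
  if (identical(k, "auto")) {
    k_range <- k_range[k_range < n]
    dd <- stats::dist(pc)
    sil <- vapply(k_range, function(kk) {
      cl <- run_km(kk)$cluster
      mean(cluster::silhouette(cl, dd)[, "sil_width"])
    }, numeric(1))
    k <- k_range[which.max(sil)]
  }
  if (k > n) .stopf("k = %d exceeds the number of cells (%d)", k, n)
  cl <- run_km(k)$cluster - 1L
  attr(cl, "k") <- as.integer(k)
  stats::setNames(cl, colnames(v))
}

#' Rank marker genes per group (one-vs-rest Wilcoxon)
#'
#' Per group, a two-sided Wilcoxon rank-sum test of each gene against all
#' other units on the test values (normal approximation with tie and
#' continuity corrections, vectorized over genes), BH adjustment within the
#' group, and a log2 fold change of depth-normalized group mean vs rest
#' mean (pseudocount 1). Markers are genes with adjusted p < 0.05 and
#' positive log2 fold change, ranked by adjusted p.
#'
#' @param counts counts `expr_matrix` (used for fold changes and, when
#'   `normalized` is NULL, log1p-normalized test values).
#' @param labels group label per unit.
#' @param normalized optional normalized `expr_matrix` whose values are
#'   used for the rank-sum tests.
#' @param top cap on reported genes per group (default Inf; tests report
#'   all genes, markers are flagged).
#' @return data.frame `group`, `gene`, `log2fc`, `p`, `padj`, `marker`,
#'   sorted within group by adjusted p.
#' @export
rank_markers <- function(counts, labels, normalized = NULL, top = Inf) {
  stopifnot(inherits(counts, "expr_matrix"))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) .stopf("at least 2 groups are required")
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    .warnf("excluding group(s) of size 1: %s", paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  norm_counts <- depth_normalize(counts$values)
  test_vals <- if (is.null(normalized)) log1p(norm_counts)
               else as.matrix(normalized$values)
  n <- ncol(test_vals)
  ranks <- t(apply(test_vals, 1, rank))
  tie_term <- apply(test_vals, 1, function(x) {
    tt <- table(x); sum(tt^3 - tt)
  })
  res <- lapply(groups, function(g) {
    in_g <- labels == g
    lfc <- log2((rowMeans(norm_counts[, in_g, drop = FALSE]) + 1) /
                (rowMeans(norm_counts[, !in_g, drop = FALSE]) + 1))
    p <- .ranksum_p(ranks, in_g, n, tie_term)
    padj <- stats::p.adjust(p, "BH")
    df <- data.frame(group = g, gene = rownames(test_vals), log2fc = lfc,
                     p = p, padj = padj,
                     marker = padj < 0.05 & lfc > 0, row.names = NULL)
    df <- df[order(df$padj, df$p, df$gene), , drop = FALSE]
    utils::head(df, top)
  })
  do.call(rbind, res)
}

# Two-sided rank-sum p (normal approximation, tie + continuity corrected),
# vectorized over the rows of a precomputed rank matrix.
.ranksum_p <- function(ranks, in_g, n, tie_term) {
  n1 <- sum(in_g); n2 <- n - n1
  w <- rowSums(ranks[, in_g, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- w - mu
  z <- z - sign(z) * 0.5
  p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

#' Assign clusters to gland parts by hypergeometric gene-set overlap
#'
#' For each cluster, the top (up to 100) markers are tested for enrichment
#' in each part's gene list against the gene-set universe (hypergeometric
#' upper tail), with BH adjustment across parts within the cluster. The
#' part with the smallest adjusted p below 0.05 wins; exact ties and empty
#' marker lists give "none".
#'
#' @param markers data.frame from [rank_markers()] with cluster groups.
#' @param geneset data.frame from [gland_gene_set()] (gene, part columns);
#'   all its genes form the test universe.
#' @param alpha significance threshold (default 0.05).
#' @param top_markers number of top markers considered per cluster (100).
#' @return data.frame `cluster`, `part`, `padj`.
#' @export
assign_clusters_to_parts <- function(markers, geneset, alpha = 0.05,
                                     top_markers = 100) {
  universe <- unique(geneset$gene)
  parts <- c("tail", "sac", "duct")
  out <- lapply(sort(unique(markers$group)), function(cl) {
    mk <- markers[markers$group == cl & markers$marker, , drop = FALSE]
    mk <- utils::head(mk$gene, top_markers)
    mk <- intersect(mk, universe)
    if (!length(mk)) {
      .warnf("cluster %s has no markers in the universe; assigning none", cl)
      return(data.frame(cluster = cl, part = "none", padj = NA_real_))
    }
    p <- vapply(parts, function(pp) {
      part_genes <- geneset$gene[geneset$part == pp]
      q <- length(intersect(mk, part_genes))
      stats::phyper(q - 1, length(part_genes),
                    length(universe) - length(part_genes), length(mk),
                    lower.tail = FALSE)
    }, numeric(1))
    padj <- stats::p.adjust(p, "BH")
    best <- which(padj == min(padj))
    part <- if (length(best) > 1 || min(padj) >= alpha) "none" else parts[best]
    data.frame(cluster = cl, part = part, padj = min(padj))
  })
  do.call(rbind, out)
}
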