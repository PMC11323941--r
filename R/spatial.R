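#' Split zone-A regions into proximal, middle, distal classes by perimeter
#'
#' Regions with perimeter below 500 pixels are proximal, above 1000 pixels
#' distal, and the rest (boundaries included) middle. Spots inherit their
#' region's class; non-A zones map to their own class (B, C) and everything
#' else to "none".
#'
#' @param spots spot table with `zone`, `region`, `perimeter` columns.
#' @param proximal_max upper bound (exclusive) for proximal (default 500).
#' @param distal_min lower bound (exclusive) for distal (default 1000).
#' @return the spot table with a `class` column added.
#' @export
split_zoneA_regions <- function(spots, proximal_max = 500, distal_min = 1000) {
  inA <- spots$zone == "A"
  missing_p <- inA & (is.na(spots$perimeter))
  if (any(missing_p))
    .stopf("zone A region(s) lacking perimeter: %s",
           paste(unique(spots$region[missing_p]), collapse = ", "))
  cls <- rep("none", nrow(spots))
  cls[inA] <- ifelse(spots$perimeter[inA] < proximal_max, "A-proximal",
              ifelse(spots$perimeter[inA] > distal_min, "A-distal", "A-middle"))
  cls[spots$zone %in% c("B", "C")] <- spots$zone[spots$zone %in% c("B", "C")]
  spots$class <- cls
  spots
}

#' Assign spots to the nearest region of their zone
#'
#' Each annotated spot is assigned to the closest (Euclidean, pixel
#' coordinates) region centroid among regions of the same section sharing
#' the spot's zone label; distance ties go to the lowest region id. Spots
#' whose zone has no region in their section stay unassigned with a warning.
#'
#' @param spots spot table with `section`, `x`, `y`, `zone`.
#' @param regions region table with `region`, `section`, `zone`, `x`, `y`,
#'   `perimeter`.
#' @return the spot table with `region` and `perimeter` columns (re)set.
#' @export
assign_spots_to_regions <- function(spots, regions) {
  spots$region <- NA_character_
  spots$perimeter <- NA_real_
  unmatched <- 0L
  for (i in seq_len(nrow(spots))) {
    if (is.na(spots$zone[i]) || spots$zone[i] == "unassigned") next
    cand <- regions[regions$section == spots$section[i] &
                    regions$zone == spots$zone[i], , drop = FALSE]
    if (!nrow(cand)) { unmatched <- unmatched + 1L; next }
    dd <- sqrt((cand$x - spots$x[i])^2 + (cand$y - spots$y[i])^2)
    cand <- cand[order(dd, cand$region), , drop = FALSE]
    spots$region[i] <- cand$region[1]
    spots$perimeter[i] <- cand$perimeter[1]
  }
  if (unmatched)
    .warnf("%d spot(s) had no region of their zone in their section", unmatched)
  spots
}

#' Marker-set expression versus cross-section perimeter
#'
#' For each marker set, the mean depth-normalized expression over the spots
#' of every zone-A region is regressed (ordinary least squares) on region
#' perimeter.
#'
#' @param spots spot table with `region`, `perimeter`, `zone`.
#' @param counts counts `expr_matrix` over the same spots.
#' @param marker_sets named list of gene-id vectors.
#' @return data.frame `set`, `slope`, `intercept`, `r`, `p`, `n_regions`;
#'   `r`/`p` are NA (flagged) when expression is constant.
#' @export
expression_perimeter_trend <- function(spots, counts, marker_sets) {
  inA <- spots$zone == "A" & !is.na(spots$region)
  spots <- spots[inA, , drop = FALSE]
  regions <- unique(spots[, c("region", "perimeter")])
  if (nrow(regions) < 3) .stopf("at least 3 zone-A regions are required")
  norm <- depth_normalize(counts$values[, spots$spot_id, drop = FALSE])
  out <- lapply(names(marker_sets), function(nm) {
    genes <- intersect(marker_sets[[nm]], rownames(norm))
    spot_mean <- colMeans(norm[genes, , drop = FALSE])
    reg_mean <- tapply(spot_mean, spots$region, mean)[regions$region]
    if (stats::sd(reg_mean) == 0)
      return(data.frame(set = nm, slope = 0, intercept = reg_mean[1],
                        r = NA_real_, p = NA_real_, n_regions = nrow(regions)))
    fit <- stats::lm(reg_mean ~ regions$perimeter)
    ct <- stats::cor.test(regions$perimeter, reg_mean)
    data.frame(set = nm, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = unname(ct$estimate), p = ct$p.value,
               n_regions = nrow(regions))
  })
  do.call(rbind, out)
}

#' Pearson correlation of hematoxylin intensity with perimeter
#'
#' @param spots spot (or region) table with `zone`, `hematoxylin`,
#'   `perimeter` columns.
#' @param zone zone restriction (default "A").
#' @return list `r`, `p`, `n`; `r` is NA (flagged undefined) under zero
#'   variance.
#' @export
hematoxylin_perimeter_correlation <- function(spots, zone = "A") {
  s <- spots[spots$zone == zone & !is.na(spots$perimeter) &
             !is.na(spots$hematoxylin), , drop = FALSE]
  if (nrow(s) < 3) .stopf("at least 3 observations are required")
  if (stats::sd(s$hematoxylin) == 0 || stats::sd(s$perimeter) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(s)))
  ct <- stats::cor.test(s$hematoxylin, s$perimeter)
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(s))
}

#' Build cell-type expression signatures for deconvolution
#'
#' A gene enters the signature when its best per-cluster average log2 fold
#' change exceeds `min_log2fc` (strict), it has at least `min_counts` total
#' counts in the spatial data, and it is detected in at least `min_spots`
#' spots. The signature is the per-type mean of depth-normalized single-cell
#' expression.
#'
#' @param cells counts `expr_matrix` of single cells.
#' @param labels cell-type label per cell.
#' @param spatial_counts counts `expr_matrix` of spots.
#' @param markers optional precomputed [rank_markers()] table; computed
#'   from `cells`/`labels` when NULL.
#' @param min_log2fc log2 fold-change floor (default 2, strict).
#' @param min_counts spatial count floor (default 200).
#' @param min_spots spot-detection floor (default 50).
#' @return genes x cell-types signature matrix.
#' @export
build_signatures <- function(cells, labels, spatial_counts, markers = NULL,
                             min_log2fc = 2, min_counts = 200, min_spots = 50) {
  if (is.null(markers)) markers <- rank_markers(cells, labels)
  best_lfc <- tapply(markers$log2fc, markers$gene, max)
  sp_tot <- Matrix::rowSums(spatial_counts$values)
  sp_det <- Matrix::rowSums(spatial_counts$values > 0)
  genes <- names(best_lfc)[best_lfc > min_log2fc]
  genes <- genes[genes %in% rownames(spatial_counts$values)]
  genes <- genes[sp_tot[genes] >= min_counts & sp_det[genes] >= min_spots]
  if (!length(genes))
    .stopf(paste0("no gene survives the signature filters ",
                  "(log2fc > %g: %d; spatial counts >= %g: %d; spots >= %g: %d)"),
           min_log2fc, sum(best_lfc > min_log2fc),
           min_counts, sum(sp_tot >= min_counts),
           min_spots, sum(sp_det >= min_spots))
  norm <- depth_normalize(cells$values)
  types <- sort(unique(as.character(labels)))
  sig <- matrix(0, length(genes), length(types),
                dimnames = list(genes, types))
  for (t in types)
    sig[, t] <- rowMeans(norm[genes, labels == t, drop = FALSE])
  zero <- rowSums(sig) == 0
  sig[!zero, , drop = FALSE]
}

#' Deconvolve spots into cell-type proportions by nonnegative least squares
#'
#' Depth-normalized spot expression (scaled to the median spot depth) is
#' regressed on the signature columns under nonnegativity; coefficients are
#' renormalized to sum to one. All-zero solutions fall back to uniform
#' proportions and are flagged.
#'
#' @param spatial_counts counts `expr_matrix` of spots.
#' @param signatures genes x types matrix from [build_signatures()].
#' @return list with `proportions` (spots x types), `residual` (per-spot
#'   residual norm), `uniform_fallback` (logical per spot).
#' @export
deconvolve_spots <- function(spatial_counts, signatures) {
  if (ncol(signatures) < 2) .stopf("at least 2 cell types are required")
  if (qr(signatures)$rank < ncol(signatures))
    .stopf("rank-deficient signature matrix; collinear types among: %s",
           paste(colnames(signatures), collapse = ", "))
  genes <- rownames(signatures)
  y <- depth_normalize(spatial_counts$values[genes, , drop = FALSE])
  n_spot <- ncol(y)
  prop <- matrix(0, n_spot, ncol(signatures),
                 dimnames = list(colnames(y), colnames(signatures)))
  resid <- numeric(n_spot)
  fallback <- logical(n_spot)
  for (i in seq_len(n_spot)) {
    fit <- pracma::lsqnonneg(signatures, y[, i])
    coefs <- fit$x
    resid[i] <- sqrt(fit$resid.norm)
    if (sum(coefs) == 0) {
      prop[i, ] <- 1 / ncol(signatures)
      fallback[i] <- TRUE
    } else prop[i, ] <- coefs / sum(coefs)
  }
  list(proportions = prop, residual = resid, uniform_fallback = fallback)
}

#' Mean cell-type proportions per positional class
#'
#' @param deconv result of [deconvolve_spots()].
#' @param spots spot table with a `class` column (see
#'   [split_zoneA_regions()]).
#' @param classes class order (default the five gland classes).
#' @return classes x types matrix of mean proportions (rows sum to 1).
#' @export
class_proportions <- function(deconv, spots,
                              classes = c("A-proximal", "A-middle",
                                          "A-distal", "B", "C")) {
  prop <- deconv$proportions
  cls <- spots$class[match(rownames(prop), spots$spot_id)]
  present <- classes[classes %in% cls]
  if (length(present) < length(classes))
    .warnf("empty class(es) omitted: %s",
           paste(setdiff(classes, present), collapse = ", "))
  out <- t(vapply(present, function(cc)
    colMeans(prop[cls == cc, , drop = FALSE]), numeric(ncol(prop))))
  rownames(out) <- present
  out
}
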