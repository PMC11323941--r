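#' Simulate bulk, single-cell, and spatial transcriptomes of the gland
#'
#' Draws negative-binomial counts for bulk tissue samples (tail, sac, duct,
#' head, body, other glands), single cells of the eight gland cell types, and
#' spatial spots whose expected expression is the mixture-weighted sum of the
#' cell-type programs for the spot's positional class along the tapering
#' tail. Marker genes are expressed at `2^marker_effect_log2` times baseline
#' in their cell type. Spot H&E intensities follow the zone means, with a
#' negative hematoxylin gradient against cross-section perimeter in zone A
#' when `he_gradient` is set.
#'
#' @param design a [make_design()] object.
#' @param seed integer master seed; one stream per assay is derived from it.
#'
#' @return A list with elements `bulk`, `cells`, `spatial` (all
#'   [expr_matrix()]), `spots` (spot table), `regions` (cross-section region
#'   table), and `truth` (a `gland_truth` object).
#' @export
simulate_transcriptomes <- function(design, seed) {
  stopifnot(inherits(design, "gland_design"))
  d <- design
  set.seed(derive_assay_seed(seed, "pipeline"))
  baseline <- stats::rlnorm(d$n_genes, d$baseline_meanlog, d$baseline_sdlog)
  # gland-program genes are highly expressed, silk-gene style
  gland_genes <- unlist(d$marker_index)
  baseline[gland_genes] <- stats::rlnorm(length(gland_genes),
                                         d$marker_baseline_meanlog,
                                         d$marker_baseline_sdlog)
  gene_lengths <- stats::setNames(
    round(stats::runif(d$n_genes, d$gene_length_range[1], d$gene_length_range[2])),
    d$gene_names)
  # per-cell-type expression programs, normalized to relative rates
  programs <- type_factor_matrix(d) * baseline
  programs <- sweep(programs, 2, colSums(programs), "/")

  bulk <- simulate_bulk(d, baseline, gene_lengths, derive_assay_seed(seed, "bulk"))
  cells <- simulate_cells(d, programs, derive_assay_seed(seed, "cells"))
  sp <- simulate_spatial(d, programs, derive_assay_seed(seed, "spatial"))

  truth <- structure(list(
    part_label = true_part_labels(d),
    zone_marker = true_zone_markers(d),
    cell_type = stats::setNames(cells$meta$true_type, cells$meta$unit),
    spot_class = stats::setNames(sp$spots$true_class, sp$spots$spot_id),
    spot_mixture = sp$mixtures,
    protein_layer = stats::setNames(d$protein_table$layer, d$protein_table$protein),
    protein_zone = stats::setNames(d$protein_table$zone, d$protein_table$protein),
    baseline = stats::setNames(baseline, d$gene_names),
    seed = as.integer(seed),
    params = list(marker_effect_log2 = d$marker_effect_log2,
                  nb_size = d$nb_size,
                  zone_mixture = d$zone_mixture)),
    class = "gland_truth")

  list(bulk = bulk, cells = cells, spatial = sp$expr, spots = sp$spots,
       regions = sp$regions, truth = truth)
}

simulate_bulk <- function(d, baseline, gene_lengths, seed) {
  set.seed(seed)
  f <- expected_bulk_factor(d)
  rate <- sweep(matrix(baseline, d$n_genes, length(d$tissues)), 1, 1, "*") * f
  rate <- sweep(rate, 2, colSums(rate), "/")
  samples <- expand.grid(rep = seq_len(d$n_reps), tissue = d$tissues,
                         stringsAsFactors = FALSE)
  samples$unit <- sprintf("%s_%d", samples$tissue, samples$rep)
  depth <- stats::rlnorm(nrow(samples), log(d$depth_mean[["bulk"]]),
                         d$depth_sdlog[["bulk"]])
  counts <- vapply(seq_len(nrow(samples)), function(i) {
    mu <- rate[, samples$tissue[i]] * depth[i]
    stats::rnbinom(d$n_genes, size = d$nb_size[["bulk"]], mu = mu)
  }, numeric(d$n_genes))
  dimnames(counts) <- list(d$gene_names, samples$unit)
  expr_matrix(counts, "counts",
              meta = data.frame(unit = samples$unit, tissue = samples$tissue,
                                replicate = samples$rep),
              gene_lengths = gene_lengths)
}

simulate_cells <- function(d, programs, seed) {
  set.seed(seed)
  n <- d$n_cells
  type <- sample(d$cell_types, n, replace = TRUE, prob = d$cell_type_probs)
  depth <- stats::rlnorm(n, log(d$depth_mean[["cells"]]), d$depth_sdlog[["cells"]])
  counts <- vapply(seq_len(n), function(i) {
    stats::rnbinom(d$n_genes, size = d$nb_size[["cells"]],
                   mu = programs[, type[i]] * depth[i])
  }, numeric(d$n_genes))
  units <- sprintf("cell_%04d", seq_len(n))
  dimnames(counts) <- list(d$gene_names, units)
  sample_id <- sprintf("ind_%d", 1L + (seq_len(n) - 1L) %% d$n_sc_samples)
  expr_matrix(Matrix::Matrix(counts, sparse = TRUE), "counts",
              meta = data.frame(unit = units, sample = sample_id,
                                true_type = type))
}

simulate_spatial <- function(d, programs, seed) {
  set.seed(seed)
  regions <- spatial_region_table(d)
  spots <- make_spot_table(d, regions)
  mixtures <- matrix(0, nrow(spots), length(d$cell_types),
                     dimnames = list(spots$spot_id, d$cell_types))
  class_mix <- rbind(d$zone_mixture,
                     duct = c(0, 0, 0, 0, 0, 0, 0.5, 0.5))
  for (i in seq_len(nrow(spots)))
    mixtures[i, ] <- class_mix[spots$true_class[i], ]
  depth <- stats::rlnorm(nrow(spots), log(d$depth_mean[["spatial"]]),
                         d$depth_sdlog[["spatial"]])
  mix_rate <- programs %*% t(mixtures)      # genes x spots
  counts <- vapply(seq_len(nrow(spots)), function(i) {
    stats::rnbinom(d$n_genes, size = d$nb_size[["spatial"]],
                   mu = mix_rate[, i] * depth[i])
  }, numeric(d$n_genes))
  dimnames(counts) <- list(d$gene_names, spots$spot_id)

  # H&E intensities: zone means plus noise; zone A hematoxylin declines with
  # cross-section perimeter when the gradient flag is on.
  zone_for_he <- ifelse(spots$zone == "duct", "C", spots$zone)
  he <- d$he_means[zone_for_he, , drop = FALSE]
  hema <- he[, "hematoxylin"] + stats::rnorm(nrow(spots), 0, d$he_sd)
  eos <- he[, "eosin"] + stats::rnorm(nrow(spots), 0, d$he_sd)
  if (isTRUE(d$he_gradient)) {
    inA <- spots$zone == "A"
    z <- scale(spots$perimeter[inA])[, 1]
    hema[inA] <- hema[inA] + d$he_gradient_coef * z
  }
  spots$hematoxylin <- hema
  spots$eosin <- eos

  em <- expr_matrix(Matrix::Matrix(counts, sparse = TRUE), "counts",
                    meta = data.frame(unit = spots$spot_id,
                                      section = spots$section))
  list(expr = em, spots = spots, regions = regions, mixtures = mixtures)
}

# Cross-section regions: the zone-A tail regions carry the design perimeters
# (strictly increasing proximal to distal); each section also holds one B,
# one C, and one duct region.
spatial_region_table <- function(d) {
  nA <- length(d$tail_perimeters)
  secA <- 1L + (seq_len(nA) - 1L) %% d$n_sections
  reg <- data.frame(
    region = sprintf("A%02d", seq_len(nA)),
    section = secA, zone = "A",
    perimeter = d$tail_perimeters,
    x = 120 * seq_len(nA), y = 150 * secA)
  extra <- do.call(rbind, lapply(seq_len(d$n_sections), function(s) {
    data.frame(region = sprintf("%s%02d", c("B", "C", "D"), s),
               section = s, zone = c("B", "C", "duct"),
               perimeter = c(1600, 1700, 420),
               x = c(2000, 2300, 2600), y = 150 * s)
  }))
  rbind(reg, extra)
}

make_spot_table <- function(d, regions) {
  per_section <- d$spots_per_section
  rows <- list()
  for (s in seq_len(d$n_sections)) {
    for (zone in names(per_section)) {
      zr <- regions[regions$section == s & regions$zone ==
                      ifelse(zone == "duct", "duct", zone), , drop = FALSE]
      if (!nrow(zr)) next
      n <- per_section[[zone]]
      ridx <- sort(sample(seq_len(nrow(zr)), n, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        section = s, zone = ifelse(zone == "duct", "duct", zone),
        region = zr$region[ridx],
        perimeter = zr$perimeter[ridx],
        x = zr$x[ridx] + stats::rnorm(n, 0, 20),
        y = zr$y[ridx] + stats::rnorm(n, 0, 20))
    }
  }
  spots <- do.call(rbind, rows)
  spots$spot_id <- sprintf("spot_%04d", seq_len(nrow(spots)))
  perim_class <- function(p) ifelse(p < 500, "A-proximal",
                             ifelse(p > 1000, "A-distal", "A-middle"))
  spots$true_class <- ifelse(spots$zone == "A", perim_class(spots$perimeter),
                      ifelse(spots$zone == "duct", "duct", spots$zone))
  spots[, c("spot_id", "section", "x", "y", "zone", "region", "perimeter",
            "true_class")]
}
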