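#' Ground-truth design of the synthetic gland, fiber, and histology
#'
#' `make_design()` assembles the generative parameters for every synthetic
#' assay: eight cell types with marker-gene programs, zone mixtures along the
#' tapering tail, negative-binomial count noise, a three-layer fiber whose
#' proteins have layer-dependent logistic extractability against urea
#' molarity, and zone-dependent H&E staining. All parameters can be
#' overridden through `config`, a nested list merged over the defaults.
#'
#' The eight cell types are, in fixed order: `ZoneA_MaSp1`, `ZoneA_MaSp2`,
#' `ZoneA_SpiCE`, `ZoneB_MaSp3`, `ZoneC_SpiCE`, `ZoneABC`, `Duct_1`,
#' `Duct_2`. The first 18 genes are the silk genes, named after the fiber
#' proteins they encode and planted as markers of their producing cell types,
#' so that the transcriptomic and proteomic halves of the pipeline share
#' identifiers.
#'
#' @param config named list of overrides; unknown names raise an error.
#'
#' @return An object of class `gland_design`.
#' @export
make_design <- function(config = list()) {
  d <- design_defaults()
  if (length(config)) {
    bad <- setdiff(names(config), names(d))
    if (length(bad)) .stopf("unknown design field(s): %s", paste(bad, collapse = ", "))
    d <- modifyList(d, config)
  }
  d <- fill_design(d)
  validate_design(d)
  class(d) <- "gland_design"
  d
}

design_defaults <- function() {
  types <- c("ZoneA_MaSp1", "ZoneA_MaSp2", "ZoneA_SpiCE", "ZoneB_MaSp3",
             "ZoneC_SpiCE", "ZoneABC", "Duct_1", "Duct_2")
  classes <- c("A-proximal", "A-middle", "A-distal", "B", "C")
  zone_mixture <- rbind(
    `A-proximal` = c(0.12, 0.60, 0.24, 0,    0,    0.04, 0, 0),
    `A-middle`   = c(0.40, 0.28, 0.28, 0,    0,    0.04, 0, 0),
    `A-distal`   = c(0.50, 0.05, 0.41, 0,    0,    0.04, 0, 0),
    B            = c(0,    0,    0,    0.87, 0,    0.13, 0, 0),
    C            = c(0,    0,    0,    0,    0.87, 0.13, 0, 0))
  colnames(zone_mixture) <- types
  # Bulk tissue composition over the eight cell types (row sums may fall
  # short of 1; the remainder is non-glandular baseline tissue). Tail
  # sections span the three zone-A positional classes; sac sections carry
  # the distal tail tip plus zones B and C and the shared ZoneABC cells;
  # duct sections are duct epithelium embedded in surrounding tissue; body
  # sections contain dilute gland tissue (the glands sit in the abdomen).
  bulk_mixing <- rbind(
    tail = colMeans(zone_mixture[1:3, ]),
    sac  = 0.06 * zone_mixture["A-distal", ] + 0.45 * zone_mixture["B", ] +
           0.34 * zone_mixture["C", ] +
           0.15 * c(0, 0, 0, 0, 0, 1, 0, 0),
    duct = c(0, 0, 0, 0, 0, 0, 0.5, 0.5),
    head = rep(0, 8),
    body = rep(0.4 / 8, 8),
    gland_other = rep(0, 8))
  colnames(bulk_mixing) <- types
  list(
    n_genes = 2000L,
    cell_types = types,
    markers_per_type = stats::setNames(c(22L, 22L, 22L, 25L, 25L, 10L, 8L, 8L), types),
    marker_effect_log2 = 3,
    gland_background_log2 = 0.8,
    positional_classes = classes,
    zone_mixture = zone_mixture,
    bulk_mixing = bulk_mixing,
    n_special_markers = c(head = 300L, body = 300L, gland_other = 300L),
    othergland_body_weight = 0.10,
    tissues = rownames(bulk_mixing),
    n_reps = 5L,
    tail_perimeters = c(250, 350, 450, 600, 750, 900, 1020, 1120, 1240, 1360, 1480),
    n_sections = 6L,
    spots_per_section = c(A = 90L, B = 25L, C = 20L, duct = 15L),
    n_cells = 3000L,
    n_sc_samples = 4L,
    cell_type_probs = stats::setNames(
      c(0.18, 0.18, 0.12, 0.14, 0.10, 0.08, 0.10, 0.10), types),
    nb_size = c(bulk = 10, cells = 2, spatial = 5),
    depth_mean = c(bulk = 5e5, cells = 2500, spatial = 5000),
    depth_sdlog = c(bulk = 0.1, cells = 0.3, spatial = 0.3),
    baseline_meanlog = log(5),
    baseline_sdlog = 1,
    marker_baseline_meanlog = log(30),
    marker_baseline_sdlog = 0.5,
    gene_length_range = c(500, 5000),
    protein_table = default_protein_table(),
    contaminants = c(no_gland = 50L, one_solvent = 50L, no_signal = 50L,
                     low_abundance = 50L),
    total_spectra = 10000L,
    ms_rep_sdlog = 0.15,
    fiber_solvents = c("HFIP", "LiBr", "urea"),
    n_ms_reps = 3L,
    urea_molarities = c(2, 4, 8),
    he_means = rbind(A = c(hematoxylin = 180, eosin = 80),
                     B = c(hematoxylin = 120, eosin = 140),
                     C = c(hematoxylin = 60,  eosin = 180)),
    he_sd = 12,
    he_gradient = TRUE,
    he_gradient_coef = -6,
    n_vesicles_per_zone = 80L,
    n_lumen_per_layer = 30L
  )
}

# The 18 fiber proteins: eight zone-A/core spidroins, four zone-B/middle
# proteins, six zone-C/outer proteins. Logistic extraction midpoints follow
# the layer (outer 1.5 M, middle 3.5 M, core 6.0 M urea; slope 0.7), so that
# mild urea preferentially solubilizes the outer layer of an intact fiber.
default_protein_table <- function() {
  tab <- data.frame(
    protein = c("MaSp1a", "MaSp1b", "MaSp1c",
                "MaSp2b", "MaSp2c", "MaSp2e", "MaSp2f", "MaSp4",
                "MaSp3a", "MaSp3b", "AmSp-like1", "AmSp-like2",
                paste0("SpiCE-LMa", 1:6)),
    length = c(3000, 3100, 2950, 2800, 2850, 2750, 2900, 1500,
               3200, 3150, 1200, 1250, 420, 460, 380, 510, 440, 400),
    signal_peptide = TRUE,
    producing_type = c(rep("ZoneA_MaSp1", 3), rep("ZoneA_MaSp2", 5),
                       rep("ZoneB_MaSp3", 2), rep("ZoneC_SpiCE", 8)),
    zone = c(rep("A", 8), rep("B", 2), rep("C", 8)),
    abundance = c(10, 10, 10, 6.5, 6.5, 6.5, 6.5, 4,
                  9, 9, 0.5, 0.5, rep(1.8, 6)),
    slope = 0.7,
    stringsAsFactors = FALSE)
  tab$layer <- c(A = "core", B = "middle", C = "outer")[tab$zone]
  tab$midpoint <- c(core = 6.0, middle = 3.5, outer = 1.5)[tab$layer]
  tab
}

# Allocate marker gene indices: contiguous blocks per cell type (the first
# genes of the zone blocks are the silk genes), then head/body/other-gland
# marker blocks, then unstructured background genes.
fill_design <- function(d) {
  nm <- sum(d$markers_per_type) + sum(d$n_special_markers)
  if (d$n_genes < nm + 15L)
    .stopf("n_genes = %d too small for %d marker genes", d$n_genes, nm)
  idx <- 1L
  marker_index <- list()
  for (t in d$cell_types) {
    k <- d$markers_per_type[[t]]
    marker_index[[t]] <- seq.int(idx, idx + k - 1L)
    idx <- idx + k
  }
  special_index <- list()
  for (s in names(d$n_special_markers)) {
    k <- d$n_special_markers[[s]]
    special_index[[s]] <- seq.int(idx, idx + k - 1L)
    idx <- idx + k
  }
  gene_names <- sprintf("g%04d", seq_len(d$n_genes))
  pt <- d$protein_table
  # silk genes sit at the head of their producing type's marker block
  silk_pos <- integer(nrow(pt))
  for (t in unique(pt$producing_type)) {
    rows <- which(pt$producing_type == t)
    silk_pos[rows] <- marker_index[[t]][seq_along(rows)]
  }
  gene_names[silk_pos] <- pt$protein
  pt$gene_index <- silk_pos
  d$protein_table <- pt
  d$marker_index <- marker_index
  d$special_index <- special_index
  d$gene_names <- gene_names
  d
}

validate_design <- function(d) {
  mix <- d$zone_mixture
  sums <- rowSums(mix)
  bad <- which(abs(sums - 1) > 1e-9 | apply(mix, 1, function(r) any(r < 0)))
  if (length(bad))
    .stopf("invalid zone_mixture for class(es) %s: proportions must be nonnegative and sum to 1",
           paste(rownames(mix)[bad], collapse = ", "))
  if (any(diff(d$tail_perimeters) <= 0))
    .stopf("tail_perimeters must be strictly increasing proximal to distal")
  if (min(d$tail_perimeters) >= 500 || max(d$tail_perimeters) <= 1000)
    .stopf("tail_perimeters must span below 500 and above 1000 pixels")
  if (d$n_genes < 200L) .stopf("n_genes must be at least 200")
  if (d$n_reps < 2L) .stopf("at least 2 replicates per tissue are required")
  pt <- d$protein_table
  if (any(!nzchar(pt$producing_type)))
    .stopf("every fiber protein needs at least one producing cell type")
  if (!all(pt$producing_type %in% d$cell_types))
    .stopf("protein producing types must be among the design cell types")
  layer_map <- c(A = "core", B = "middle", C = "outer")
  if (!all(pt$layer == layer_map[pt$zone]))
    .stopf("protein layer/zone mapping must be core-A, middle-B, outer-C")
  if (d$total_spectra <= 0) .stopf("total spectra per sample must be positive")
  invisible(d)
}

#' @export
print.gland_design <- function(x, ...) {
  cat(sprintf(paste0("<gland_design> %d genes, %d cell types, %d tail regions, ",
                     "%d fiber proteins + %d contaminants\n"),
              x$n_genes, length(x$cell_types), length(x$tail_perimeters),
              nrow(x$protein_table), sum(x$contaminants)))
  invisible(x)
}

# Expression factor of every gene in every gland cell type, relative to
# baseline. Gland-program genes (markers of any of the eight types) carry a
# gland-wide background of 2^gland_background_log2 in every gland cell and
# rise to 2^marker_effect_log2 in their own type; silk-gland genes are
# gland-enriched throughout the epithelium with a relative zone preference,
# and the gene-set filter classifies by that preference.
type_factor_matrix <- function(d) {
  f <- matrix(1, d$n_genes, length(d$cell_types),
              dimnames = list(d$gene_names, d$cell_types))
  gland_genes <- unlist(d$marker_index)
  f[gland_genes, ] <- 2^d$gland_background_log2
  for (t in d$cell_types)
    f[d$marker_index[[t]], t] <- 2^d$marker_effect_log2
  f
}

# Expected bulk expression factor (relative to baseline) per gene per tissue:
# the cell-type mixture of each tissue applied to the type factors, with the
# remaining tissue fraction at baseline. Head-, body-, and other-gland-
# specific genes are modeled at the tissue level.
expected_bulk_factor <- function(d) {
  tf <- type_factor_matrix(d)
  f <- matrix(1, d$n_genes, length(d$tissues),
              dimnames = list(d$gene_names, d$tissues))
  for (tis in d$tissues) {
    w <- d$bulk_mixing[tis, ]
    f[, tis] <- drop(tf %*% w) + (1 - sum(w))
  }
  gain <- 2^d$marker_effect_log2 - 1
  f[d$special_index$head, "head"] <- 1 + gain
  f[d$special_index$body, "body"] <- 1 + gain
  f[d$special_index$gland_other, "gland_other"] <- 1 + gain
  f[d$special_index$gland_other, "body"] <-
    1 + gain * d$othergland_body_weight
  f
}

#' Planted part label per gene
#'
#' The gland part (tail/sac/duct) where a gene's expected bulk expression is
#' maximal; "none" when no part dominates the runner-up by at least `ratio`.
#' This is the generative ground truth the gene-set filter is scored against.
#'
#' @param d a [make_design()] object.
#' @param ratio dominance ratio (default 1.5).
#' @return named character vector over genes.
#' @export
true_part_labels <- function(d, ratio = 1.5) {
  f <- expected_bulk_factor(d)[, c("tail", "sac", "duct")]
  lab <- rep("none", d$n_genes)
  ord <- t(apply(f, 1, sort, decreasing = TRUE))
  dominated <- ord[, 1] / ord[, 2] >= ratio
  lab[dominated] <- colnames(f)[max.col(f)[dominated]]
  stats::setNames(lab, d$gene_names)
}

#' Planted zone markerhood per gene (A, B, C, or none)
#'
#' @param d a [make_design()] object.
#' @return named character vector over genes, derived from the producing
#'   cell type's zone.
#' @export
true_zone_markers <- function(d) {
  zone_of_type <- c(ZoneA_MaSp1 = "A", ZoneA_MaSp2 = "A", ZoneA_SpiCE = "A",
                    ZoneB_MaSp3 = "B", ZoneC_SpiCE = "C", ZoneABC = "none",
                    Duct_1 = "none", Duct_2 = "none")
  z <- rep("none", d$n_genes)
  for (t in d$cell_types) z[d$marker_index[[t]]] <- zone_of_type[[t]]
  stats::setNames(z, d$gene_names)
}
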