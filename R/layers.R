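#' Relative urea solubilization profiles of identified proteins
#'
#' Percent of total spectra recomputed over the identified proteins only
#' (restricted-set renormalization), then averaged over replicates per urea
#' molarity.
#'
#' @param fiber `spectra_table` of a urea molarity series (one preparation).
#' @param proteins character vector of identified silk proteins.
#' @param molarities required molarities (default 2, 4, 8).
#' @return list with `mean` (proteins x molarities), `replicates`
#'   (proteins x samples relative abundance), `meta` (sample metadata).
#' @export
relative_urea_profiles <- function(fiber, proteins, molarities = c(2, 4, 8)) {
  stopifnot(inherits(fiber, "spectra_table"))
  have <- unique(fiber$meta$molarity)
  if (!all(molarities %in% have))
    .stopf("missing molarity series: %s M",
           paste(setdiff(molarities, have), collapse = ", "))
  sub <- subset_spectra(fiber, samples = fiber$meta$molarity %in% molarities,
                        proteins = proteins)
  rel <- percent_total_spectra(sub)
  mol <- sub$meta$molarity
  mean_rel <- matrix(0, length(proteins), length(molarities),
                     dimnames = list(proteins, paste0(molarities, "M")))
  for (j in seq_along(molarities))
    mean_rel[, j] <- rowMeans(rel[, mol == molarities[j], drop = FALSE])
  list(mean = mean_rel, replicates = rel, meta = sub$meta)
}

#' Classify proteins by urea enrichment (2 M vs 8 M)
#'
#' Two-sided Welch t-test of per-replicate relative abundances at 2 M
#' against 8 M, BH-adjusted across the tested proteins. Significant and
#' higher at 2 M: `enriched-2M`; significant and higher at 8 M:
#' `enriched-8M`; not significant with the 4 M mean strictly maximal:
#' `peak-4M`; otherwise `unclassified`.
#'
#' @param profiles result of [relative_urea_profiles()].
#' @param alpha significance level on adjusted p (default 0.05).
#' @param adjust apply BH adjustment across proteins (default TRUE).
#' @param peak_margin required excess of the 4 M mean over the runner-up
#'   for `peak-4M` (default 0).
#' @return data.frame `protein`, `t`, `p`, `padj`, `mean_2M`, `mean_4M`,
#'   `mean_8M`, `urea_class`.
#' @export
urea_enrichment_test <- function(profiles, alpha = 0.05, adjust = TRUE,
                                 peak_margin = 0) {
  rel <- profiles$replicates
  mol <- profiles$meta$molarity
  if (sum(mol == 2) < 2 || sum(mol == 8) < 2)
    .stopf("at least 2 replicates at 2 M and 8 M are required")
  stat <- t(apply(rel, 1, function(x) {
    a <- x[mol == 2]; b <- x[mol == 8]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      c(t = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf,
        p = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
      c(t = unname(tt$statistic), p = tt$p.value)
    }
  }))
  padj <- if (adjust) stats::p.adjust(stat[, "p"], "BH") else stat[, "p"]
  m <- profiles$mean
  cls <- character(nrow(rel))
  for (i in seq_len(nrow(rel))) {
    if (padj[i] < alpha && stat[i, "t"] > 0) cls[i] <- "enriched-2M"
    else if (padj[i] < alpha && stat[i, "t"] < 0) cls[i] <- "enriched-8M"
    else if (m[i, "4M"] > max(m[i, c("2M", "8M")]) + peak_margin)
      cls[i] <- "peak-4M"
    else cls[i] <- "unclassified"
  }
  data.frame(protein = rownames(rel), t = stat[, "t"], p = stat[, "p"],
             padj = padj, mean_2M = m[, "2M"], mean_4M = m[, "4M"],
             mean_8M = m[, "8M"], urea_class = cls, row.names = NULL)
}

#' Compare intact and formic-acid-dissolved urea extracts
#'
#' Pairwise Pearson correlation between all urea-series samples (intact and
#' dissolved) over per-sample relative abundance vectors of the identified
#' proteins; average-linkage hierarchical clustering on distance 1 - r; and
#' a per-protein Welch t-test of 2 M intact against 2 M dissolved relative
#' abundance.
#'
#' @param intact,dissolved `spectra_table`s of the two urea series.
#' @param proteins identified silk proteins.
#' @return list with `correlation` (samples x samples), `dendrogram`
#'   (hclust), `newick` (character), `contrasts` (per-protein data.frame).
#' @export
intact_vs_dissolved_compare <- function(intact, dissolved, proteins) {
  ri <- relative_urea_profiles(intact, proteins)
  rd <- relative_urea_profiles(dissolved, proteins)
  mat <- cbind(ri$replicates, rd$replicates)
  prep <- c(rep("intact", ncol(ri$replicates)),
            rep("dissolved", ncol(rd$replicates)))
  keep <- apply(mat, 2, stats::sd) > 0
  if (any(!keep))
    .warnf("excluding zero-variance sample(s): %s",
           paste(colnames(mat)[!keep], collapse = ", "))
  mat <- mat[, keep, drop = FALSE]
  cc <- stats::cor(mat)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  m2i <- ri$meta$molarity == 2
  m2d <- rd$meta$molarity == 2
  contrasts <- t(apply(cbind(ri$replicates[, m2i, drop = FALSE],
                             rd$replicates[, m2d, drop = FALSE]), 1,
    function(x) {
      a <- x[seq_len(sum(m2i))]; b <- x[-seq_len(sum(m2i))]
      if (length(a) < 2 || length(b) < 2) return(c(t = NA_real_, p = NA_real_))
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        c(t = 0, p = if (mean(a) == mean(b)) 1 else 0)
      else { tt <- stats::t.test(a, b); c(t = unname(tt$statistic), p = tt$p.value) }
    }))
  list(correlation = cc, dendrogram = hc, newick = nwk,
       contrasts = data.frame(protein = rownames(contrasts),
                              t = contrasts[, "t"], p = contrasts[, "p"],
                              row.names = NULL),
       preparation = stats::setNames(prep[keep], colnames(mat)))
}

#' Match lumen layers to zones by H&E intensity
#'
#' Hematoxylin and eosin intensities are jointly standardized; zone
#' centroids come from vesicle objects; each lumen-layer object is assigned
#' to the nearest centroid and each layer to the majority zone of its
#' objects. Majority ties leave the layer unmapped.
#'
#' @param histo HistoTable as from [simulate_histology()].
#' @return data.frame `layer`, `zone`, `vote_fraction`, `n_objects`.
#' @export
histo_match_layers <- function(histo) {
  ves <- histo[histo$compartment == "vesicle", , drop = FALSE]
  lum <- histo[histo$compartment == "lumen-layer", , drop = FALSE]
  if (any(table(ves$zone) < 3)) .stopf("at least 3 vesicle objects per zone are required")
  if (!nrow(lum)) .stopf("at least 1 lumen object per layer is required")
  h <- scale(histo$hematoxylin); e <- scale(histo$eosin)
  xy <- cbind(h, e)
  rownames(xy) <- histo$object_id
  zones <- sort(unique(ves$zone))
  centroids <- t(vapply(zones, function(z)
    colMeans(xy[histo$object_id %in% ves$object_id[ves$zone == z], ,
                drop = FALSE]), numeric(2)))
  assign_one <- function(id) {
    dd <- sqrt(rowSums(sweep(centroids, 2, xy[id, ], "-")^2))
    best <- which(dd == min(dd))
    if (length(best) > 1) NA_character_ else zones[best]
  }
  lum$assigned_zone <- vapply(lum$object_id, assign_one, character(1))
  out <- lapply(sort(unique(lum$layer)), function(l) {
    zz <- lum$assigned_zone[lum$layer == l]
    zz <- zz[!is.na(zz)]
    tab <- sort(table(zz), decreasing = TRUE)
    tie <- length(tab) > 1 && tab[1] == tab[2]
    if (!length(tab) || tie) {
      .warnf("layer %s: majority tie or no assignable objects; unmapped", l)
      data.frame(layer = l, zone = NA_character_, vote_fraction = NA_real_,
                 n_objects = length(zz))
    } else data.frame(layer = l, zone = names(tab)[1],
                      vote_fraction = tab[[1]] / length(zz),
                      n_objects = length(zz))
  })
  do.call(rbind, out)
}

#' Assemble the zone-to-layer model of the fiber
#'
#' Combines per-protein zone-of-origin calls (from zone-marker analysis),
#' urea enrichment classes, and the histology layer-zone mapping into the
#' final layer model: zone A maps to the fiber core, B to the middle and C
#' to the outer layer. `consistency` records whether the urea class agrees
#' with the zone mapping (8 M with core, 4 M peak with middle, 2 M with
#' outer). Proteins with a "mixed" zone but a classified urea profile take
#' their layer from the urea class and are flagged inconsistent; proteins
#' missing from the zone input are "unresolved".
#'
#' @param zone_of_origin named character vector (A/B/C/mixed) per protein.
#' @param urea_classes data.frame from [urea_enrichment_test()].
#' @param histo_mapping optional data.frame from [histo_match_layers()]
#'   (reported alongside; does not alter assignments).
#' @return object of class `layer_model`: a data.frame `protein`,
#'   `zone_of_origin`, `urea_class`, `layer`, `consistency` plus supporting
#'   statistics; the histology mapping is attached as an attribute.
#' @export
build_layer_model <- function(zone_of_origin, urea_classes,
                              histo_mapping = NULL) {
  zone_layer <- c(A = "core", B = "middle", C = "outer")
  urea_layer <- c(`enriched-8M` = "core", `peak-4M` = "middle",
                  `enriched-2M` = "outer", unclassified = NA_character_)
  prot <- urea_classes$protein
  zoo <- zone_of_origin[prot]
  zoo[is.na(zoo)] <- "unresolved"
  layer <- character(length(prot))
  consistent <- logical(length(prot))
  for (i in seq_along(prot)) {
    uc <- urea_classes$urea_class[i]
    if (zoo[i] %in% names(zone_layer)) {
      layer[i] <- zone_layer[[zoo[i]]]
      consistent[i] <- identical(urea_layer[[uc]], layer[i])
    } else if (zoo[i] == "mixed" && !is.na(urea_layer[[uc]])) {
      layer[i] <- urea_layer[[uc]]
      consistent[i] <- FALSE
    } else {
      layer[i] <- "unresolved"
      consistent[i] <- FALSE
    }
  }
  out <- data.frame(protein = prot, zone_of_origin = unname(zoo),
                    urea_class = urea_classes$urea_class, layer = layer,
                    consistency = consistent,
                    t = urea_classes$t, padj = urea_classes$padj,
                    mean_2M = urea_classes$mean_2M,
                    mean_4M = urea_classes$mean_4M,
                    mean_8M = urea_classes$mean_8M, row.names = NULL)
  attr(out, "histo_mapping") <- histo_mapping
  class(out) <- c("layer_model", "data.frame")
  out
}

#' Zone of origin of identified proteins from zone-marker statistics
#'
#' For each protein's gene, the zone (A, B, C) with the smallest adjusted
#' marker p-value (requiring marker status: adjusted p < alpha and positive
#' fold change); "mixed" when no zone is significant.
#'
#' @param zone_markers [rank_markers()] table computed over zone labels.
#' @param proteins character vector of protein (= gene) identifiers.
#' @param alpha significance level (default 0.05).
#' @return named character vector of zones per protein.
#' @export
zone_of_origin_from_markers <- function(zone_markers, proteins, alpha = 0.05) {
  zm <- zone_markers[zone_markers$group %in% c("A", "B", "C"), , drop = FALSE]
  vapply(proteins, function(p) {
    rows <- zm[zm$gene == p & zm$padj < alpha & zm$log2fc > 0, , drop = FALSE]
    if (!nrow(rows)) "mixed" else rows$group[which.min(rows$padj)]
  }, character(1))
}
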