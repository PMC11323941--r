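#' Simulate H&E histology intensities for vesicles and lumen layers
#'
#' Vesicle objects draw (hematoxylin, eosin) pairs from their zone's mean
#' with Gaussian noise; lumen-layer objects (layers I, II, III, numbered from
#' the innermost) draw from the mean of their originating zone (I from A,
#' II from B, III from C). When the design's `he_gradient` flag is set, the
#' zone-A vesicle hematoxylin mean declines with the perimeter of the tail
#' region the vesicle sits in.
#'
#' @param design a [make_design()] object.
#' @param seed integer seed.
#' @return A data.frame (HistoTable) with columns `object_id`, `compartment`
#'   (`vesicle`/`lumen-layer`), `zone`, `layer`, `perimeter`, `hematoxylin`,
#'   `eosin`.
#' @export
simulate_histology <- function(design, seed) {
  stopifnot(inherits(design, "gland_design"))
  d <- design
  if (d$n_vesicles_per_zone < 10L || d$n_lumen_per_layer < 1L)
    .stopf("at least 10 vesicle objects per zone are required")
  set.seed(derive_assay_seed(seed, "histology"))
  zones <- rownames(d$he_means)
  nv <- d$n_vesicles_per_zone
  ves <- do.call(rbind, lapply(zones, function(z) {
    perim <- if (z == "A")
      sample(d$tail_perimeters, nv, replace = TRUE) else NA_real_
    h <- d$he_means[z, "hematoxylin"] + stats::rnorm(nv, 0, d$he_sd)
    if (z == "A" && isTRUE(d$he_gradient) && stats::sd(perim) > 0)
      h <- h + d$he_gradient_coef * scale(perim)[, 1]
    data.frame(compartment = "vesicle", zone = z, layer = NA_character_,
               perimeter = perim, hematoxylin = h,
               eosin = d$he_means[z, "eosin"] + stats::rnorm(nv, 0, d$he_sd))
  }))
  layer_zone <- c(I = "A", II = "B", III = "C")
  nl <- d$n_lumen_per_layer
  lum <- do.call(rbind, lapply(names(layer_zone), function(l) {
    z <- layer_zone[[l]]
    data.frame(compartment = "lumen-layer", zone = NA_character_, layer = l,
               perimeter = NA_real_,
               hematoxylin = d$he_means[z, "hematoxylin"] +
                 stats::rnorm(nl, 0, d$he_sd),
               eosin = d$he_means[z, "eosin"] + stats::rnorm(nl, 0, d$he_sd))
  }))
  out <- rbind(ves, lum)
  out$object_id <- sprintf("obj_%04d", seq_len(nrow(out)))
  out[, c("object_id", "compartment", "zone", "layer", "perimeter",
          "hematoxylin", "eosin")]
}

#' Synthesize protein sequences for the design's proteins
#'
#' Spidroin-like proteins are assembled from silk repeat units (poly-alanine
#' blocks, GGX and GPGXX motifs, spacers) to their annotated length;
#' contaminants and SpiCE-like proteins are random sequences with a generic
#' globular composition. Sequence lengths match the annotated lengths.
#'
#' @param design a [make_design()] object.
#' @param seed integer seed.
#' @return named character vector of amino-acid sequences (silk proteins plus
#'   contaminants).
#' @export
protein_sequences <- function(design, seed) {
  stopifnot(inherits(design, "gland_design"))
  set.seed(derive_assay_seed(seed, "sequences"))
  pt <- design$protein_table
  con <- contaminant_table(design)
  units <- c("AAAAAA", "AAAAA", "GGA", "GGQ", "GGY", "GPGQQ", "GPGGY",
             "GSQGS", "SQGAG")
  globular <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                "S","T","V","W","Y")
  spidroin <- function(len) {
    body <- paste(sample(units, ceiling(len / 3), replace = TRUE),
                  collapse = "")
    paste0("M", substr(body, 1, len - 1))
  }
  random_seq <- function(len)
    paste(sample(globular, len, replace = TRUE), collapse = "")
  silk <- vapply(seq_len(nrow(pt)), function(i) {
    if (grepl("^MaSp|^AmSp", pt$protein[i])) spidroin(pt$length[i])
    else random_seq(pt$length[i])
  }, character(1))
  seqs <- c(silk, vapply(con$length, random_seq, character(1)))
  stats::setNames(seqs, c(pt$protein, con$protein))
}
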