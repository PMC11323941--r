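#' Write a complete synthetic dataset bundle to disk
#'
#' Serializes all pipeline inputs in plain-text formats: bulk counts as TSV,
#' single-cell and spatial counts as MatrixMarket with gene/unit sidecars,
#' spot/region/spectra/histology tables as CSV, protein sequences as FASTA,
#' signal-peptide flags as CSV, ground truth as JSON, and a manifest (YAML)
#' naming every role.
#'
#' @param sim result of [simulate_transcriptomes()].
#' @param spectra result of [simulate_proteomics()].
#' @param histo result of [simulate_histology()].
#' @param sequences named character vector from [protein_sequences()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_bundle <- function(sim, spectra, histo, sequences, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_tsv <- function(x, path) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)

  bulk <- as.matrix(sim$bulk$values)
  utils::write.table(data.frame(gene = rownames(bulk), bulk, check.names = FALSE),
                     fp("bulk_counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv(sim$bulk$meta, fp("bulk_meta.tsv"))
  write_tsv(data.frame(gene = names(sim$bulk$gene_lengths),
                       length = unname(sim$bulk$gene_lengths)),
            fp("gene_lengths.tsv"))

  write_mtx <- function(em, stem) {
    Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), fp(paste0(stem, ".mtx")))
    writeLines(rownames(em$values), fp(paste0(stem, "_genes.tsv")))
    writeLines(colnames(em$values), fp(paste0(stem, "_units.tsv")))
    utils::write.csv(em$meta, fp(paste0(stem, "_meta.csv")), row.names = FALSE)
  }
  write_mtx(sim$cells, "cells")
  write_mtx(sim$spatial, "spatial")
  utils::write.csv(sim$spots, fp("spots.csv"), row.names = FALSE)
  utils::write.csv(sim$regions, fp("regions.csv"), row.names = FALSE)

  utils::write.csv(data.frame(protein = rownames(spectra$counts),
                              spectra$counts, check.names = FALSE),
                   fp("spectra_counts.csv"), row.names = FALSE)
  utils::write.csv(spectra$meta, fp("spectra_meta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(protein = rownames(spectra$counts),
                              length = unname(spectra$lengths),
                              signal_peptide =
                                spectra$protein_meta$signal_peptide),
                   fp("protein_flags.csv"), row.names = FALSE)
  utils::write.csv(histo, fp("histology.csv"), row.names = FALSE)

  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, fp("proteins.fasta"))

  jsonlite::write_json(truth_to_list(sim$truth), fp("truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- list(
    bulk_counts = "bulk_counts.tsv", bulk_meta = "bulk_meta.tsv",
    gene_lengths = "gene_lengths.tsv",
    cells = "cells.mtx", cells_genes = "cells_genes.tsv",
    cells_units = "cells_units.tsv", cells_meta = "cells_meta.csv",
    spatial = "spatial.mtx", spatial_genes = "spatial_genes.tsv",
    spatial_units = "spatial_units.tsv", spatial_meta = "spatial_meta.csv",
    spots = "spots.csv", regions = "regions.csv",
    spectra_counts = "spectra_counts.csv", spectra_meta = "spectra_meta.csv",
    protein_flags = "protein_flags.csv", fasta = "proteins.fasta",
    histology = "histology.csv", truth = "truth.json")
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  invisible(fp("manifest.yaml"))
}

truth_to_list <- function(truth) {
  list(part_label = as.list(truth$part_label),
       zone_marker = as.list(truth$zone_marker),
       cell_type = as.list(truth$cell_type),
       spot_class = as.list(truth$spot_class),
       spot_mixture = list(values = apply(truth$spot_mixture, 2, identity,
                                          simplify = FALSE),
                           spots = rownames(truth$spot_mixture),
                           types = colnames(truth$spot_mixture)),
       protein_layer = as.list(truth$protein_layer),
       protein_zone = as.list(truth$protein_zone),
       baseline = as.list(truth$baseline),
       seed = truth$seed,
       params = list(marker_effect_log2 = truth$params$marker_effect_log2,
                     nb_size = as.list(truth$params$nb_size),
                     zone_mixture = list(
                       values = apply(truth$params$zone_mixture, 2, identity,
                                      simplify = FALSE),
                       classes = rownames(truth$params$zone_mixture),
                       types = colnames(truth$params$zone_mixture))))
}

list_to_truth <- function(x) {
  unlist_named <- function(l) unlist(l)
  mixmat <- function(m) {
    mm <- do.call(cbind, lapply(m$values, function(col) unlist(col, use.names = FALSE)))
    dimnames(mm) <- list(if (!is.null(m$spots)) unlist(m$spots) else
      unlist(m$classes), unlist(m$types))
    mm
  }
  structure(list(
    part_label = unlist_named(x$part_label),
    zone_marker = unlist_named(x$zone_marker),
    cell_type = unlist_named(x$cell_type),
    spot_class = unlist_named(x$spot_class),
    spot_mixture = mixmat(x$spot_mixture),
    protein_layer = unlist_named(x$protein_layer),
    protein_zone = unlist_named(x$protein_zone),
    baseline = unlist_named(x$baseline),
    seed = as.integer(x$seed),
    params = list(marker_effect_log2 = x$params$marker_effect_log2,
                  nb_size = unlist_named(x$params$nb_size),
                  zone_mixture = mixmat(x$params$zone_mixture))),
    class = "gland_truth")
}

#' Read a gland_truth object back from JSON
#' @param path path to a truth JSON file.
#' @return a `gland_truth` object.
#' @export
read_truth <- function(path) {
  list_to_truth(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Load a dataset bundle from a manifest
#'
#' Reads every input named by the manifest, reassembles the package
#' containers, and validates identifier consistency: gene identifiers must
#' agree across bulk, single-cell and spatial inputs, and protein
#' identifiers across the spectra table, FASTA and flag file (strict by
#' default).
#'
#' @param manifest path to a manifest YAML written by [write_bundle()].
#' @return a list (DatasetBundle) with elements `bulk`, `cells`, `spatial`,
#'   `spots`, `regions`, `spectra`, `flags`, `sequences`, `histology`,
#'   `truth`.
#' @export
load_bundle <- function(manifest) {
  if (!file.exists(manifest)) .stopf("manifest not found: %s", manifest)
  m <- yaml::read_yaml(manifest)
  base <- dirname(manifest)
  path <- function(role) {
    if (is.null(m[[role]])) .stopf("manifest is missing required role '%s'", role)
    p <- file.path(base, m[[role]])
    if (!file.exists(p)) .stopf("missing file for role '%s': %s", role, p)
    p
  }
  bulk_raw <- utils::read.delim(path("bulk_counts"), check.names = FALSE)
  bulk_counts <- as.matrix(bulk_raw[, -1, drop = FALSE])
  rownames(bulk_counts) <- bulk_raw$gene
  lengths_df <- utils::read.delim(path("gene_lengths"))
  bulk <- expr_matrix(bulk_counts, "counts",
                      meta = utils::read.delim(path("bulk_meta")),
                      gene_lengths = stats::setNames(lengths_df$length,
                                                     lengths_df$gene))
  read_mtx <- function(stem) {
    v <- as(Matrix::readMM(path(stem)), "CsparseMatrix")
    rownames(v) <- readLines(path(paste0(stem, "_genes")))
    colnames(v) <- readLines(path(paste0(stem, "_units")))
    expr_matrix(v, "counts",
                meta = utils::read.csv(path(paste0(stem, "_meta"))))
  }
  cells <- read_mtx("cells")
  spatial <- read_mtx("spatial")
  for (what in list(c("single-cell", "cells"), c("spatial", "spatial"))) {
    g <- rownames(get(what[2])$values)
    miss <- setdiff(g, rownames(bulk_counts))
    if (length(miss))
      .stopf("%d %s gene(s) absent from bulk counts: %s", length(miss),
             what[1], paste(utils::head(miss, 5), collapse = ", "))
  }
  spots <- utils::read.csv(path("spots"))
  regions <- utils::read.csv(path("regions"))
  sc_raw <- utils::read.csv(path("spectra_counts"), check.names = FALSE)
  counts <- as.matrix(sc_raw[, -1, drop = FALSE])
  rownames(counts) <- sc_raw$protein
  flags_df <- utils::read.csv(path("protein_flags"))
  spectra <- spectra_table(counts, utils::read.csv(path("spectra_meta")),
                           stats::setNames(flags_df$length, flags_df$protein))
  seqs <- Biostrings::readAAStringSet(path("fasta"))
  sequences <- stats::setNames(as.character(seqs), names(seqs))
  mismatch <- setdiff(rownames(counts), names(sequences))
  if (length(mismatch))
    .stopf("%d protein(s) missing from FASTA: %s", length(mismatch),
           paste(utils::head(mismatch, 5), collapse = ", "))
  truth <- if (!is.null(m$truth) &&
               file.exists(file.path(base, m$truth)))
    read_truth(file.path(base, m$truth)) else NULL
  list(bulk = bulk, cells = cells, spatial = spatial, spots = spots,
       regions = regions, spectra = spectra,
       flags = stats::setNames(flags_df$signal_peptide, flags_df$protein),
       sequences = sequences, histology = utils::read.csv(path("histology")),
       truth = truth, manifest = manifest)
}

#' Run the full inference pipeline on a dataset bundle
#'
#' Executes the stages in order — gland gene set (TPM prefilter, two
#' sign-oriented PCA steps, loading-distance step, PLS-DA, differential
#' expression), single cell (QC, normalization, clustering, markers, part
#' assignment), spatial (QC, region split/assignment, zone markers,
#' perimeter trends, deconvolution, class proportions), proteomics
#' (quantification and silk-protein identification), and layer inference
#' (urea enrichment, intact-vs-dissolved control, histology matching, layer
#' model) — writing per-stage tables and a LayerModel JSON under `outdir`.
#'
#' @param bundle a [load_bundle()] result (or the in-memory equivalent).
#' @param config named list of stage parameters; recognized entries include
#'   `distance_cutoff`, `k_clusters`, `rescue_genes`, `min_mean_pct`,
#'   `stages` (character subset to run), and `seed`.
#' @param outdir output directory (default `tempfile("ampulla_run")`).
#' @return list of per-stage results, invisibly; outputs on disk.
#' @export
run_pipeline <- function(bundle, config = list(), outdir = tempfile("ampulla_run")) {
  cfg <- modifyList(list(distance_cutoff = 0.33, k_clusters = 8,
                         rescue_genes = character(), min_mean_pct = 0.15,
                         min_cells_per_sample = 500, seed = 1L,
                         stages = c("geneset", "sc", "spatial", "proteomics",
                                    "layers")),
                    config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] stage=%s %s\n", format(Sys.time(), "%H:%M:%S"),
                stage, msg),
        file = file.path(outdir, "run.log"), append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
    log_line(stage, sprintf("elapsed=%.1fs", as.numeric(Sys.time() - t0,
                                                        units = "secs")))
    out
  }

  if ("geneset" %in% cfg$stages) {
    res$geneset <- run_stage("geneset", {
      counts <- tpm_prefilter(bundle$bulk)
      vst <- vst_counts(counts)
      s1 <- pca_sign_filter(vst, groups = list("head", "body"), gland_side = 2)
      vst1 <- subset_expr(vst, genes = s1)
      rescue <- cfg$rescue_genes
      if (is.null(rescue)) rescue <- character()
      s2 <- pca_sign_filter(vst1,
                            groups = list(c("tail", "sac", "duct"), "body"),
                            gland_side = 1, rescue = rescue)
      gland_units <- vst$meta$unit[vst$meta$tissue %in% c("tail", "sac", "duct")]
      vst2 <- subset_expr(vst, genes = s2, units = gland_units)
      gs <- gland_gene_set(vst2, cutoff = cfg$distance_cutoff)
      model <- plsda(vst2, seed = cfg$seed)
      de <- lapply(stats::setNames(nm = c("tail", "sac", "duct")), function(p)
        differential_expression(subset_expr(counts, genes = s2,
                                            units = gland_units), p))
      utils::write.table(gs, file.path(outdir, "gene_set.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      for (p in names(de))
        utils::write.table(de[[p]], file.path(outdir, sprintf("de_%s.tsv", p)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(steps = list(step1 = s1, step2 = s2), gene_set = gs,
           plsda = model, de = de)
    })
  }

  if ("sc" %in% cfg$stages) {
    res$sc <- run_stage("sc", {
      qc <- qc_filter(bundle$cells,
                      min_cells_per_sample = cfg$min_cells_per_sample)
      normed <- normalize_cells(qc$cells)
      cl <- cluster_cells(normed, k = cfg$k_clusters, seed = cfg$seed)
      markers <- rank_markers(qc$cells, cl, normalized = normed)
      parts <- assign_clusters_to_parts(markers, res$geneset$gene_set)
      cell_table <- qc$cell_table[qc$cell_table$kept, , drop = FALSE]
      cell_table$cluster <- cl[cell_table$cell]
      cell_table$part <- parts$part[match(cell_table$cluster, parts$cluster)]
      utils::write.csv(cell_table, file.path(outdir, "cell_table.csv"),
                       row.names = FALSE)
      utils::write.table(markers[markers$marker, ],
                         file.path(outdir, "sc_markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(qc = qc, normalized = normed, clusters = cl, markers = markers,
           parts = parts, cell_table = cell_table)
    })
  }

  if ("spatial" %in% cfg$stages) {
    res$spatial <- run_stage("spatial", {
      sqc <- qc_filter(bundle$spatial, min_cells_per_sample = 0)
      spots <- bundle$spots[bundle$spots$spot_id %in% sqc$cells$meta$unit, ,
                            drop = FALSE]
      spots <- assign_spots_to_regions(spots, bundle$regions)
      spots <- split_zoneA_regions(spots)
      zone_spots <- spots[spots$zone %in% c("A", "B", "C"), , drop = FALSE]
      zcounts <- subset_expr(sqc$cells, units = zone_spots$spot_id)
      zone_markers <- rank_markers(zcounts, zone_spots$zone)
      cl <- res$sc$clusters
      type_markers <- res$sc$markers[res$sc$markers$marker, , drop = FALSE]
      marker_sets <- split(type_markers$gene, type_markers$group)
      trend <- expression_perimeter_trend(spots, sqc$cells, marker_sets)
      hp <- hematoxylin_perimeter_correlation(spots)
      sig <- build_signatures(res$sc$qc$cells, cl, sqc$cells,
                              markers = res$sc$markers)
      dec <- deconvolve_spots(subset_expr(sqc$cells,
                                          units = zone_spots$spot_id), sig)
      cp <- class_proportions(dec, spots)
      utils::write.csv(spots, file.path(outdir, "spot_table.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(spot = rownames(dec$proportions),
                                  dec$proportions, check.names = FALSE),
                       file.path(outdir, "deconvolution.csv"),
                       row.names = FALSE)
      utils::write.table(data.frame(class = rownames(cp), cp,
                                    check.names = FALSE),
                         file.path(outdir, "class_proportions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(spots = spots, zone_markers = zone_markers, trend = trend,
           hematoxylin = hp, signatures = sig, deconv = dec,
           class_proportions = cp)
    })
  }

  if ("proteomics" %in% cfg$stages) {
    res$proteomics <- run_stage("proteomics", {
      gland <- subset_spectra(bundle$spectra,
                              samples = bundle$spectra$meta$source == "gland")
      fib <- fiber_id_samples(bundle$spectra)
      id <- identify_silk_proteins(gland, fib, bundle$flags,
                                   threshold = cfg$min_mean_pct)
      utils::write.table(id, file.path(outdir, "silk_evidence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(evidence = id, silk = attr(id, "silk"),
           pct = percent_total_spectra(fib), nsaf = nsaf(fib))
    })
  }

  if ("layers" %in% cfg$stages) {
    res$layers <- run_stage("layers", {
      silk <- res$proteomics$silk
      intact <- urea_series(bundle$spectra, "intact")
      dissolved <- urea_series(bundle$spectra, "dissolved")
      prof <- relative_urea_profiles(intact, silk)
      uc <- urea_enrichment_test(prof)
      ivd <- intact_vs_dissolved_compare(intact, dissolved, silk)
      hm <- histo_match_layers(bundle$histology)
      zoo <- zone_of_origin_from_markers(res$spatial$zone_markers, silk)
      model <- build_layer_model(zoo, uc, hm)
      jsonlite::write_json(model, file.path(outdir, "layer_model.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.csv(ivd$correlation,
                       file.path(outdir, "urea_correlation.csv"))
      writeLines(ivd$newick, file.path(outdir, "urea_dendrogram.nwk"))
      list(profiles = prof, urea_classes = uc, intact_vs_dissolved = ivd,
           histo_mapping = hm, model = model)
    })
  }
  invisible(res)
}

#' Simulate, write, and reload a complete synthetic bundle
#'
#' Convenience wrapper chaining [make_design()], the three simulators,
#' [write_bundle()] and [load_bundle()].
#'
#' @param config design overrides for [make_design()].
#' @param seed master seed.
#' @param dir bundle directory (default a tempdir).
#' @return a loaded bundle.
#' @export
simulate_bundle <- function(config = list(), seed, dir = tempfile("bundle")) {
  design <- make_design(config)
  sim <- simulate_transcriptomes(design, seed)
  spectra <- simulate_proteomics(design, seed)
  histo <- simulate_histology(design, seed)
  seqs <- protein_sequences(design, seed)
  manifest <- write_bundle(sim, spectra, histo, seqs, dir)
  load_bundle(manifest)
}
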