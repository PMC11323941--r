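toy_spots <- function() {
  data.frame(
    spot_id = sprintf("s%02d", 1:6), section = 1,
    x = c(0, 10, 100, 110, 200, 210), y = 0,
    zone = c("A", "A", "A", "A", "B", "duct"),
    region = NA_character_,
    perimeter = NA_real_,
    hematoxylin = c(180, 175, 170, 160, 120, 100),
    eosin = 80)
}

toy_regions <- function() {
  data.frame(region = c("A01", "A02", "A03", "B01", "D01"),
             section = 1, zone = c("A", "A", "A", "B", "duct"),
             x = c(0, 100, 200, 205, 210), y = 0,
             perimeter = c(400, 750, 1500, 1600, 420))
}

test_that("perimeter thresholds split zone A strictly", {
  spots <- assign_spots_to_regions(toy_spots(), toy_regions())
  out <- split_zoneA_regions(spots)
  expect_identical(out$class[out$region == "A01"],
                   rep("A-proximal", sum(out$region == "A01")))
  expect_identical(unique(out$class[out$region == "A02"]), "A-middle")
  distal <- toy_spots()[1, ]; distal$x <- 195
  distal <- split_zoneA_regions(assign_spots_to_regions(distal,
                                                        toy_regions()))
  expect_identical(distal$class, "A-distal")
  # boundary perimeters 500 and 1000 are middle
  b <- toy_spots()[1:2, ]; b$region <- c("A01", "A02")
  b$perimeter <- c(500, 1000)
  expect_identical(split_zoneA_regions(b)$class,
                   c("A-middle", "A-middle"))
  miss <- toy_spots()[1, ]; miss$region <- "A09"
  expect_error(split_zoneA_regions(miss), "A09")
})

test_that("spots go to the nearest same-zone region with a deterministic tie rule", {
  spots <- assign_spots_to_regions(toy_spots(), toy_regions())
  expect_identical(spots$region[1:4], c("A01", "A01", "A02", "A02"))
  expect_identical(spots$region[5], "B01")
  expect_identical(spots$region[6], "D01")
  # tie: equidistant between A02 (x=100) and A03 (x=200) -> lower id
  tie <- toy_spots()[1, ]; tie$x <- 150
  expect_identical(assign_spots_to_regions(tie, toy_regions())$region, "A02")
  # zone-B spot never lands in a zone-A region
  bspot <- toy_spots()[5, ]; bspot$x <- 0
  expect_identical(assign_spots_to_regions(bspot, toy_regions())$region, "B01")
  orphan <- toy_spots()[5, ]; orphan$section <- 2
  expect_warning(out <- assign_spots_to_regions(orphan, toy_regions()),
                 "no region")
  expect_true(is.na(out$region))
})

test_that("marker-set perimeter trends recover planted gradients with OLS", {
  d <- make_design()
  sim <- simulate_transcriptomes(d, 2)
  spots <- split_zoneA_regions(assign_spots_to_regions(sim$spots,
                                                       sim$regions))
  sets <- lapply(d$marker_index[c("ZoneA_MaSp1", "ZoneA_MaSp2")],
                 function(i) d$gene_names[i])
  tr <- expression_perimeter_trend(spots, sim$spatial, sets)
  expect_gt(tr$slope[tr$set == "ZoneA_MaSp1"], 0)
  expect_lt(tr$slope[tr$set == "ZoneA_MaSp2"], 0)
  expect_true(all(tr$p < 0.05))
  # reference OLS on the same region means
  inA <- spots$zone == "A"
  norm <- depth_normalize(sim$spatial$values[, spots$spot_id[inA]])
  sm <- colMeans(norm[sets$ZoneA_MaSp1, ])
  rm_ <- tapply(sm, spots$region[inA], mean)
  per <- sim$regions$perimeter[match(names(rm_), sim$regions$region)]
  ref <- lm(as.numeric(rm_) ~ per)
  expect_equal(tr$slope[tr$set == "ZoneA_MaSp1"], unname(coef(ref)[2]),
               tolerance = 1e-9)
  # constant expression flags an undefined correlation
  const <- matrix(5, 2, sum(inA))
  rownames(const) <- c("k1", "k2"); colnames(const) <- spots$spot_id[inA]
  cem <- expr_matrix(const, "counts")
  tr0 <- expression_perimeter_trend(spots[inA, ], cem, list(flat = "k1"))
  expect_true(is.na(tr0$r))
  expect_equal(tr0$slope, 0)
})

test_that("hematoxylin-perimeter correlation matches the direct formula", {
  spots <- data.frame(zone = "A", hematoxylin = c(10, 8, 6, 4),
                      perimeter = c(1, 2, 3, 4))
  out <- hematoxylin_perimeter_correlation(spots)
  expect_equal(out$r, -1)
  const <- transform(spots, hematoxylin = 5)
  expect_true(is.na(hematoxylin_perimeter_correlation(const)$r))
  sim <- simulate_transcriptomes(make_design(), 3)
  sp <- sim$spots[sim$spots$zone == "A", ]
  set.seed(1)
  sp80 <- sp[sample(nrow(sp), 80), ]
  out80 <- hematoxylin_perimeter_correlation(sp80)
  expect_lt(out80$r, 0)
  expect_lt(out80$p, 0.05)
  expect_equal(out80$n, 80)
  r_ref <- cor(sp80$hematoxylin, sp80$perimeter)
  expect_equal(out80$r, r_ref, tolerance = 1e-12)
})

test_that("signature filters apply the documented boundary readings", {
  markers <- data.frame(group = rep(c("t1", "t2"), each = 3),
                        gene = rep(c("g1", "g2", "g3"), 2),
                        log2fc = c(2.0, 2.5, 3.0, 2.5, 0.5, 2.0),
                        p = 0.001, padj = 0.001, marker = TRUE)
  sp <- matrix(0L, 3, 60)
  rownames(sp) <- c("g1", "g2", "g3")
  colnames(sp) <- sprintf("s%02d", 1:60)
  sp["g1", 1:50] <- 4L          # 200 counts in 50 spots -> kept
  sp["g2", 1:49] <- 5L          # 245 counts in 49 spots -> dropped (spots)
  sp["g3", 1:50] <- 3L          # 150 counts in 50 spots -> dropped (counts)
  spem <- expr_matrix(sp, "counts")
  cells <- matrix(c(8, 1, 2, 2, 8, 2), 3, 2,
                  dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  cem <- expr_matrix(cells, "counts",
                     meta = data.frame(unit = c("c1", "c2")))
  sig <- build_signatures(cem, c("t1", "t2"), spem, markers = markers)
  expect_identical(rownames(sig), "g1")     # g1: max lfc 2.5 > 2, filters pass
  # strict > 2: a gene whose best lfc is exactly 2 is dropped
  m2 <- transform(markers, log2fc = c(2.0, 2.0, 2.0, 1.0, 0.5, 2.0))
  expect_error(build_signatures(cem, c("t1", "t2"), spem, markers = m2),
               "no gene survives")
})

test_that("NNLS deconvolution is exact on noiseless mixtures and flags fallbacks", {
  set.seed(8)
  sig <- matrix(runif(60 * 3, 1, 10), 60, 3,
                dimnames = list(sprintf("g%02d", 1:60), c("t1", "t2", "t3")))
  mix <- c(0.5, 0.5, 0)
  y <- drop(sig %*% mix)
  target <- stats::median(c(sum(y), sum(sig[, 1])))
  spots <- cbind(spot1 = round(y * 50), spot2 = round(sig[, 1] * 50))
  em <- expr_matrix(spots, "counts")
  dec <- deconvolve_spots(em, sig)
  expect_equal(unname(dec$proportions["spot1", ]), mix, tolerance = 0.01)
  expect_equal(unname(dec$proportions["spot2", ]), c(1, 0, 0),
               tolerance = 0.01)
  expect_true(all(abs(rowSums(dec$proportions) - 1) < 1e-9))
  expect_true(all(dec$proportions >= 0))
  # collinear signature columns are refused
  bad <- sig; bad[, 3] <- 2 * bad[, 1]
  expect_error(deconvolve_spots(em, bad), "collinear")
})

test_that("class proportions average per positional class and warn on empties", {
  prop <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("t1", "t2")))
  spots <- data.frame(spot_id = c("s1", "s2"),
                      class = c("A-proximal", "B"))
  expect_warning(cp <- class_proportions(list(proportions = prop), spots),
                 "omitted")
  expect_equal(unname(cp["A-proximal", ]), c(0.6, 0.4))
  expect_true(all(abs(rowSums(cp) - 1) < 1e-9))
})

test_that("end-to-end class argmax matches the planted dominant cell type", {
  d <- make_design()
  sim <- simulate_transcriptomes(d, 4)
  qc <- qc_filter(sim$cells, min_cells_per_sample = 0)
  r <- normalize_cells(qc$cells)
  cl <- cluster_cells(r, k = 8, seed = 1)
  mk <- rank_markers(qc$cells, cl, normalized = r)
  sig <- build_signatures(qc$cells, cl, sim$spatial, markers = mk)
  spots <- split_zoneA_regions(assign_spots_to_regions(sim$spots,
                                                       sim$regions))
  zs <- spots[spots$zone %in% c("A", "B", "C"), ]
  dec <- deconvolve_spots(subset_expr(sim$spatial, units = zs$spot_id), sig)
  cp <- class_proportions(dec, spots)
  truth <- sim$truth$cell_type[names(cl)]
  major <- apply(table(truth, cl), 2, function(x)
    rownames(table(truth, cl))[which.max(x)])
  got <- major[colnames(cp)[apply(cp, 1, which.max)]]
  planted <- apply(d$zone_mixture, 1, function(w)
    d$cell_types[which.max(w)])
  expect_identical(unname(got), unname(planted[rownames(cp)]))
})
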