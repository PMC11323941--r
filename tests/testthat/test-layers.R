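urea_toy <- function(counts, molarity, preparation = "intact") {
  toy_spectra(counts, solvent = "urea", molarity = molarity,
              preparation = rep(preparation, ncol(counts)))
}

test_that("relative urea profiles renormalize over the identified set", {
  counts <- rbind(P1 = c(10, 20, 40, 80, 160, 320),
                  P2 = c(10, 20, 40, 80, 160, 320),
                  CON = c(5, 5, 5, 5, 5, 5))
  st <- urea_toy(counts, molarity = rep(c(2, 4, 8), each = 2))
  prof <- relative_urea_profiles(st, c("P1", "P2"))
  expect_true(all(abs(prof$mean - 50) < 1e-9))
  single <- relative_urea_profiles(st, "P1")
  expect_true(all(single$mean == 100))
  expect_error(relative_urea_profiles(
    urea_toy(counts[, 1:4], rep(c(2, 4), each = 2)), "P1"), "8")
})

test_that("urea enrichment classes follow the Welch test and the 4M peak rule", {
  rel <- rbind(E2 = c(30, 31, 29, 10, 11, 9) / 100,
               E8 = c(10, 11, 9, 30, 31, 29) / 100,
               P4 = c(20, 19, 21, 20, 21, 19) / 100,
               UN = c(40, 39, 41, 40, 37, 43) / 100)
  meta <- data.frame(molarity = rep(c(2, 8), each = 3))
  m4 <- cbind(`2M` = rowMeans(rel[, 1:3]),
              `4M` = c(0.15, 0.15, 0.30, 0.39),
              `8M` = rowMeans(rel[, 4:6]))
  prof <- list(replicates = rel, meta = meta, mean = m4)
  out <- urea_enrichment_test(prof)
  expect_identical(out$urea_class,
                   c("enriched-2M", "enriched-8M", "peak-4M", "unclassified"))
  # p matches the reference Welch t-test
  p_ref <- t.test(rel["E2", 1:3], rel["E2", 4:6])$p.value
  expect_equal(out$p[1], p_ref, tolerance = 1e-12)
  expect_true(all(diff(out$padj[order(out$p)]) >= 0))
  # identical values in both groups -> unclassified unless 4M strictly peaks
  flat <- list(replicates = rbind(F1 = rep(0.5, 6)), meta = meta,
               mean = cbind(`2M` = 0.5, `4M` = 0.5, `8M` = 0.5))
  expect_identical(urea_enrichment_test(flat)$urea_class, "unclassified")
  peak <- list(replicates = rbind(F1 = rep(0.5, 6)), meta = meta,
               mean = cbind(`2M` = 0.5, `4M` = 0.6, `8M` = 0.5))
  expect_identical(urea_enrichment_test(peak)$urea_class, "peak-4M")
})

test_that("synthetic layer profiles behave as built: core rises with molarity", {
  d <- small_design()
  sp <- simulate_proteomics(d, 1)
  silk <- d$protein_table$protein
  prof <- relative_urea_profiles(urea_series(sp, "intact"), silk)
  core <- d$protein_table$protein[d$protein_table$layer == "core"]
  for (p in core)
    expect_true(all(diff(prof$mean[p, c("2M", "4M", "8M")]) > 0))
})

test_that("intact vs dissolved comparison is a valid correlation analysis", {
  d <- small_design()
  sp <- simulate_proteomics(d, 5)
  silk <- d$protein_table$protein
  cmp <- intact_vs_dissolved_compare(urea_series(sp, "intact"),
                                     urea_series(sp, "dissolved"), silk)
  cc <- cmp$correlation
  expect_equal(unname(diag(cc)), rep(1, nrow(cc)))
  expect_equal(cc, t(cc), tolerance = 1e-12)
  # manual Pearson for one pair
  ri <- relative_urea_profiles(urea_series(sp, "intact"), silk)$replicates
  expect_equal(cc[colnames(ri)[1], colnames(ri)[2]],
               cor(ri[, 1], ri[, 2]), tolerance = 1e-12)
  # intact 2M samples resemble each other more than dissolved 2M samples
  prep <- cmp$preparation
  mol <- c(relative_urea_profiles(urea_series(sp, "intact"), silk)$meta$molarity,
           relative_urea_profiles(urea_series(sp, "dissolved"), silk)$meta$molarity)
  names(mol) <- names(prep)
  at2 <- names(prep)[mol[names(prep)] == 2]
  within <- c(); between <- c()
  for (a in at2) for (b in at2) if (a < b) {
    if (prep[a] == prep[b]) within <- c(within, cc[a, b])
    else between <- c(between, cc[a, b])
  }
  expect_gt(mean(within), mean(between))
  expect_match(cmp$newick, "^\\(")
  # duplicated samples correlate exactly and merge first
  dup <- rbind(P1 = c(10L, 10L, 20L, 40L),
               P2 = c(90L, 90L, 80L, 60L))
  ti <- urea_toy(dup, c(2, 2, 4, 8))
  td <- urea_toy(dup[, c(1, 3, 4)], c(2, 4, 8), "dissolved")
  cmp2 <- intact_vs_dissolved_compare(ti, td, c("P1", "P2"))
  expect_equal(unname(cmp2$correlation[1, 2]), 1)
})

test_that("lumen layers map to zones by nearest vesicle centroid with tie rule", {
  d <- small_design(he_sd = 4)
  h <- simulate_histology(d, 3)
  map <- histo_match_layers(h)
  expect_identical(map$zone[match(c("I", "II", "III"), map$layer)],
                   c("A", "B", "C"))
  expect_true(all(map$vote_fraction > 0.8))
  # an object exactly at a centroid is assigned to it; ties are unmapped
  ves <- data.frame(object_id = sprintf("v%d", 1:6),
                    compartment = "vesicle",
                    zone = rep(c("A", "B"), each = 3),
                    layer = NA_character_,
                    hematoxylin = rep(c(10, 20), each = 3),
                    eosin = rep(c(10, 20), each = 3))
  lum <- data.frame(object_id = c("l1", "l2"), compartment = "lumen-layer",
                    zone = NA_character_, layer = c("I", "II"),
                    hematoxylin = c(10, 15), eosin = c(10, 15))
  hh <- rbind(cbind(ves, perimeter = NA_real_),
              cbind(lum, perimeter = NA_real_))
  expect_warning(map2 <- histo_match_layers(hh), "unmapped")
  expect_identical(map2$zone[map2$layer == "I"], "A")
  expect_true(is.na(map2$zone[map2$layer == "II"]))
})

test_that("the layer model maps zones to layers and flags inconsistencies", {
  uc <- data.frame(protein = c("a", "b", "c", "d", "e"),
                   t = c(-5, 2, 5, 5, 1), p = 0.01, padj = c(0.01, 0.2, 0.01,
                                                             0.01, 0.6),
                   mean_2M = c(1, 5, 30, 30, 5),
                   mean_4M = c(5, 30, 10, 10, 6),
                   mean_8M = c(30, 10, 2, 2, 5),
                   urea_class = c("enriched-8M", "peak-4M", "enriched-2M",
                                  "enriched-2M", "unclassified"))
  zoo <- c(a = "A", b = "B", c = "C", d = "mixed")
  lm <- build_layer_model(zoo, uc)
  expect_identical(lm$layer, c("core", "middle", "outer", "outer",
                               "unresolved"))
  expect_identical(lm$consistency, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(lm$zone_of_origin[5], "unresolved")
  expect_equal(nrow(lm), 5)
})

test_that("layer recovery holds on the default fiber and ignores the control", {
  d <- small_design()
  correct <- c(); middle_ok <- c()
  for (seed in 1:6) {
    sp <- simulate_proteomics(d, seed)
    silk <- d$protein_table$protein
    prof <- relative_urea_profiles(urea_series(sp, "intact"), silk)
    uc <- urea_enrichment_test(prof)
    zoo <- setNames(d$protein_table$zone, silk)
    lm <- build_layer_model(zoo, uc)
    correct <- c(correct,
                 mean(lm$layer == d$protein_table$layer & lm$consistency))
    middle_ok <- c(middle_ok,
                   all(lm$urea_class[d$protein_table$layer == "middle"] ==
                         "peak-4M"))
  }
  expect_gte(mean(correct), 0.9)
  expect_gte(sum(middle_ok), 5L)
})

test_that("zone of origin comes from the most significant zone marker", {
  zm <- data.frame(group = c("A", "B", "A"),
                   gene = c("P1", "P1", "P2"),
                   log2fc = c(2, 1, -1), p = c(1e-6, 1e-3, 1e-8),
                   padj = c(1e-5, 1e-2, 1e-7), marker = TRUE)
  zoo <- zone_of_origin_from_markers(zm, c("P1", "P2", "P3"))
  expect_identical(unname(zoo), c("A", "mixed", "mixed"))
})
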