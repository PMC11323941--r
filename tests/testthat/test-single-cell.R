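make_cells <- function(n_genes = 60, n_cells = 60, depth = 1000,
                       n_types = 2, markers_per_type = 5, effect = 4,
                       seed = 1, size = 20) {
  set.seed(seed)
  type <- rep(seq_len(n_types), length.out = n_cells)
  mu <- matrix(depth / n_genes, n_genes, n_cells)
  for (t in seq_len(n_types)) {
    rows <- (t - 1) * markers_per_type + seq_len(markers_per_type)
    mu[rows, type == t] <- mu[rows, type == t] * 2^effect
  }
  v <- matrix(rnbinom(length(mu), mu = mu, size = size), n_genes)
  rownames(v) <- sprintf("g%03d", seq_len(n_genes))
  colnames(v) <- sprintf("c%03d", seq_len(n_cells))
  list(em = expr_matrix(v, "counts",
                        meta = data.frame(unit = colnames(v),
                                          sample = "s1")),
       type = type)
}

test_that("QC boundaries are strict on genes/counts and sample size", {
  v <- matrix(0L, 400, 5)
  v[1:299, 1] <- 3L                       # 299 genes, 897 counts -> removed
  v[1:300, 2] <- 2L; v[300, 2] <- 0L      # 299 genes -> removed
  v[1:300, 3] <- 2L                       # 300 genes, 600 counts -> kept
  v[1:250, 4] <- 2L                       # 250 genes, 500 counts -> removed
  v[1:300, 5] <- 1L; v[1:200, 5] <- 2L    # 300 genes, 500 counts -> kept
  rownames(v) <- sprintf("g%03d", 1:400)
  colnames(v) <- sprintf("c%d", 1:5)
  em <- expr_matrix(v, "counts",
                    meta = data.frame(unit = colnames(v), sample = "s1"))
  qc <- qc_filter(em, min_cells_per_sample = 0)
  expect_setequal(colnames(qc$cells$values), c("c3", "c5"))
  # sample retention: strictly more than the threshold survives
  v2 <- cbind(v, v[, c(3, 5)])
  colnames(v2) <- c(colnames(v), "d1", "d2")
  v2[, "d2"] <- v[, 4]                    # second s2 cell fails cell QC
  em2 <- expr_matrix(v2, "counts",
                     meta = data.frame(unit = colnames(v2),
                                       sample = rep(c("s1", "s2"), c(5, 2))))
  qc2 <- qc_filter(em2, min_cells_per_sample = 1)
  expect_true(all(qc2$cells$meta$sample == "s1"))   # s2 kept 1 cell, not > 1
  expect_error(qc_filter(em, min_genes = 1000), "every cell")
})

test_that("Pearson residuals are near zero for model-conforming genes and clipped", {
  set.seed(5)
  depth <- rep(c(500, 1000, 2000), each = 20)
  rate <- rep(1 / 50, 50)
  v <- sapply(depth, function(d) rpois(50, d * rate))
  rownames(v) <- sprintf("g%02d", 1:50)
  colnames(v) <- sprintf("c%02d", seq_along(depth))
  em <- expr_matrix(v, "counts")
  r <- normalize_cells(em)
  expect_lt(max(abs(rowMeans(r$values))), 0.1)
  expect_lte(max(abs(r$values)), sqrt(ncol(v)))
  # an overexpressed subset pushes residuals up inside the subset
  cells <- make_cells(effect = 3)
  rr <- normalize_cells(cells$em)
  in1 <- cells$type == 1
  expect_gt(mean(rr$values[1, in1]), mean(rr$values[1, !in1]))
})

test_that("k-means clustering recovers well-separated types deterministically", {
  cells <- make_cells(n_cells = 80, effect = 4)
  r <- normalize_cells(cells$em)
  cl <- cluster_cells(r, k = 2, n_pcs = 10, seed = 1)
  expect_equal(ari(cl, cells$type), 1.0)
  expect_identical(cl, cluster_cells(r, k = 2, n_pcs = 10, seed = 1))
  expect_error(cluster_cells(r, k = 100, seed = 1), "exceeds")
  expect_error(cluster_cells(r, k = 2), "seed")
})

test_that("silhouette auto-k finds the planted number of cell types", {
  hits <- 0L
  for (seed in 1:6) {
    d <- small_design(n_cells = 800L)
    sim <- simulate_transcriptomes(d, seed)
    r <- normalize_cells(sim$cells)
    cl <- cluster_cells(r, k = "auto", seed = seed, k_range = 5:11)
    if (attr(cl, "k") == 8L) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("marker ranking matches the reference rank-sum test and its contract", {
  cells <- make_cells(n_cells = 40, effect = 3, seed = 9)
  r <- normalize_cells(cells$em)
  mk <- rank_markers(cells$em, cells$type, normalized = r)
  # flat gene is never a marker
  flat <- mk[mk$gene == "g060", ]
  expect_true(all(!flat$marker))
  # planted marker tops its group
  g1 <- mk[mk$group == "1", ]
  expect_true(g1$gene[1] %in% sprintf("g%03d", 1:5))
  expect_true(all(diff(g1$padj) >= 0))
  # p-values equal wilcox.test with normal approximation + corrections
  x <- r$values["g001", ]
  p_ref <- suppressWarnings(
    wilcox.test(x[cells$type == 1], x[cells$type != 1],
                exact = FALSE, correct = TRUE)$p.value)
  expect_equal(g1$p[g1$gene == "g001"], p_ref, tolerance = 1e-9)
  expect_warning(rank_markers(cells$em, c(rep("a", 39), "b")), "size 1")
})

test_that("cluster-to-part assignment is hypergeometric with a strict tie rule", {
  geneset <- data.frame(
    gene = sprintf("g%03d", 1:60),
    part = rep(c("tail", "sac", "duct"), each = 20))
  mk <- data.frame(group = 0L, gene = sprintf("g%03d", 1:10),
                   log2fc = 2, p = 1e-6, padj = 1e-6, marker = TRUE)
  out <- assign_clusters_to_parts(mk, geneset)
  expect_identical(out$part, "tail")
  q <- 10; m <- 20; n <- 40; k <- 10
  p_manual <- sum(choose(m, q:k) * choose(n, k - (q:k))) / choose(m + n, k)
  expect_equal(out$padj, p.adjust(c(phyper(q - 1, m, n, k, lower.tail = FALSE),
                                    phyper(-1, 20, 40, 10, lower.tail = FALSE),
                                    phyper(-1, 20, 40, 10, lower.tail = FALSE)),
                                  "BH")[1])
  expect_equal(phyper(q - 1, m, n, k, lower.tail = FALSE), p_manual,
               tolerance = 1e-12)
  # markers disjoint from the universe -> none, with warning
  mk2 <- transform(mk, gene = sprintf("x%03d", 1:10))
  expect_warning(out2 <- assign_clusters_to_parts(mk2, geneset), "none")
  expect_identical(out2$part, "none")
  # exact symmetric overlap -> none
  mk3 <- data.frame(group = 0L, gene = sprintf("g%03d", c(1:5, 21:25)),
                    log2fc = 2, p = 1e-6, padj = 1e-6, marker = TRUE)
  out3 <- assign_clusters_to_parts(mk3, geneset)
  expect_identical(out3$part, "none")
})

test_that("the eight planted cell types are recovered and assigned to parts", {
  d <- small_design(n_cells = 900L)
  sim <- simulate_transcriptomes(d, 3)
  qc <- qc_filter(sim$cells, min_cells_per_sample = 0)
  r <- normalize_cells(qc$cells)
  cl <- cluster_cells(r, k = 8, seed = 1)
  truth <- sim$truth$cell_type[names(cl)]
  expect_gte(ari(cl, truth), 0.9)
  mk <- rank_markers(qc$cells, cl, normalized = r)
  gg <- run_geneset_filter(sim)
  parts <- assign_clusters_to_parts(mk, gg$gene_set)
  major <- apply(table(truth, cl), 2, function(x)
    rownames(table(truth, cl))[which.max(x)])
  expected <- c(ZoneA_MaSp1 = "tail", ZoneA_MaSp2 = "tail",
                ZoneA_SpiCE = "tail", ZoneB_MaSp3 = "sac",
                ZoneC_SpiCE = "sac", ZoneABC = "sac",
                Duct_1 = "duct", Duct_2 = "duct")
  agree <- parts$part == expected[major[as.character(parts$cluster)]]
  expect_gte(mean(agree), 7 / 8)
})
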