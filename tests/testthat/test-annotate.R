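test_that("normalization scales cells to the target and log-transforms", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(2, 2),
                            dims = c(3, 2),
                            dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  m["g1", "c2"] <- 5
  norm <- suppressWarnings(normalize_log(m, target_sum = 4))
  # cell c1: counts (2,2,0) scaled to total 4 -> (2,2,0) -> log1p
  expect_equal(norm["g1", "c1"], log(3))
  expect_equal(norm["g2", "c1"], log(3))
  expect_equal(norm["g3", "c1"], 0)  # all-zero gene stays zero
  # pre-log totals all equal the target
  expect_equal(unname(Matrix::colSums(expm1(as.matrix(norm)))), c(4, 4),
               tolerance = 1e-12)
})

test_that("all-zero cells are flagged and excluded", {
  m <- Matrix::sparseMatrix(i = 1, j = 1, x = 3, dims = c(2, 2),
                            dimnames = list(c("g1", "g2"), c("keep", "empty")))
  expect_warning(norm <- normalize_log(m), "all-zero")
  expect_identical(colnames(norm), "keep")
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(2, 1),
                                dimnames = list(c("g1", "g2"), "only"))
  expect_error(suppressWarnings(normalize_log(empty)), "no cells")
})

test_that("clustering separates well-separated populations and is reproducible", {
  d <- simulate_dataset(two_pop_config(pA = 0.5, n_cells_per_sample = 100,
                                       fold = 50, groups = c("g1", "g1"),
                                       nb_dispersion = 0.2))
  norm <- normalize_log(d$counts)
  labs <- cluster_cells(norm, resolution = 0.5, seed = 1)
  truth <- d$truth$major_type[match(colnames(norm), d$truth$cell_id)]
  expect_identical(length(unique(labs)), 2L)
  expect_equal(mclust::adjustedRandIndex(labs, truth), 1)
  expect_identical(cluster_cells(norm, resolution = 0.5, seed = 1), labs)
  # k-means fallback with a requested center count
  km <- cluster_cells(norm, resolution = 2, seed = 1, method = "kmeans")
  expect_equal(mclust::adjustedRandIndex(km, truth), 1)
})

test_that("degenerate inputs collapse to one cluster", {
  m <- matrix(1, nrow = 5, ncol = 10,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  expect_identical(unname(cluster_cells(m)), rep(1L, 10))
})

test_that("cluster scores reflect marker structure and its symmetries", {
  ref <- marker_reference("mp", list(Macrophages = "m1", Monocytes = "m2",
                                     MatureDCs = "m3", cDC1 = "m4",
                                     cDC2 = "m5"))
  # two clusters with swapped marker blocks give a permuted score table
  m <- dense_norm(0, 6, 40, gene_prefix = "m")
  rownames(m) <- paste0("m", 1:6)
  m["m1", 1:20] <- 3; m["m2", 21:40] <- 3
  labels <- rep(1:2, each = 20)
  sc <- score_cluster_types(m, labels, ref)
  expect_equal(sc["1", "Macrophages"], sc["2", "Monocytes"])
  expect_equal(sc["2", "Macrophages"], sc["1", "Monocytes"])
  expect_gt(sc["1", "Macrophages"], sc["1", "Monocytes"])
  # constant matrix: zero-variance z-scores are defined as 0
  flat <- dense_norm(2, 6, 10, gene_prefix = "m")
  rownames(flat) <- paste0("m", 1:6)
  sc0 <- score_cluster_types(flat, rep(1:2, each = 5), ref)
  expect_true(all(sc0 == 0))
  # missing markers warn; a fully absent type errors with its name
  ref2 <- marker_reference("mp", list(Macrophages = c("m1", "nope"),
                                      Monocytes = "m2", MatureDCs = "m3",
                                      cDC1 = "m4", cDC2 = "m5"))
  expect_warning(score_cluster_types(m, labels, ref2), "absent")
  ref3 <- marker_reference("mp", list(Macrophages = "gone", Monocytes = "m2",
                                      MatureDCs = "m3", cDC1 = "m4",
                                      cDC2 = "m5"))
  expect_error(suppressWarnings(score_cluster_types(m, labels, ref3)),
               "Macrophages")
})

test_that("type assignment takes the argmax and flags lexicographic ties", {
  tab <- matrix(c(1.0, 0.2, 0.5, 0.5), nrow = 2, byrow = TRUE,
                dimnames = list(c("1", "2"), c("B", "A")))
  out <- assign_types(tab)
  expect_identical(out$type, c("B", "A"))  # tie in cluster 2 goes to "A"
  expect_identical(out$tie, c(FALSE, TRUE))
})

test_that("hierarchical annotation recovers planted labels at modest size", {
  d <- simulate_dataset(default_config("major13", n_cells_per_sample = 220,
                                       n_genes = 600, seed = 2))
  meta <- d$truth[, c("cell_id", "sample_id", "group")]
  ann <- suppressWarnings(annotate_hierarchy(d$counts, meta, seed = 1))
  truth <- d$truth$major_type[match(ann$cell_id, d$truth$cell_id)]
  expect_gte(mclust::adjustedRandIndex(ann$major_type, truth), 0.9)
  # nullability invariants
  expect_true(all(is.na(ann$mp_subtype) | ann$major_type == "MPs"))
  expect_true(all(is.na(ann$macro_subtype) |
                    (!is.na(ann$mp_subtype) & ann$mp_subtype == "Macrophages")))
})

test_that("annotation is invariant to cell order permutation", {
  d <- simulate_dataset(default_config("mp5", n_cells_per_sample = 60,
                                       n_genes = 400, seed = 4))
  meta <- d$truth[, c("cell_id", "sample_id", "group")]
  ann1 <- suppressWarnings(annotate_hierarchy(d$counts, meta,
                                              start_level = "mp", seed = 1))
  perm <- withr::with_seed(9, sample(ncol(d$counts)))
  ann2 <- suppressWarnings(annotate_hierarchy(d$counts[, perm], meta,
                                              start_level = "mp", seed = 1))
  ann2 <- ann2[match(ann1$cell_id, ann2$cell_id), ]
  expect_identical(ann1$mp_subtype, ann2$mp_subtype)
})

test_that("a dataset without MPs leaves the subtype levels empty", {
  cfg <- default_config("major13", n_cells_per_sample = 80, n_genes = 600,
                        seed = 6)
  for (g in names(cfg$group_proportions)) {
    p <- cfg$group_proportions[[g]]
    p["MPs"] <- 0
    cfg$group_proportions[[g]] <- p / sum(p)
  }
  d <- simulate_dataset(cfg)
  meta <- d$truth[, c("cell_id", "sample_id", "group")]
  ann <- suppressWarnings(annotate_hierarchy(d$counts, meta, seed = 1))
  expect_true(all(is.na(ann$mp_subtype)))
  expect_true(all(is.na(ann$macro_subtype)))
})

test_that("top_markers recovers planted markers and handles boundaries", {
  d <- simulate_dataset(default_config("macro6", n_cells_per_sample = 80,
                                       n_genes = 400, seed = 8))
  norm <- normalize_log(d$counts)
  labels <- d$truth$macro_subtype[match(colnames(norm), d$truth$cell_id)]
  top <- top_markers(norm, labels, n = 10)
  cfg <- default_config("macro6")
  for (ty in names(cfg$populations)) {
    planted <- cfg$populations[[ty]]
    found <- top$gene[top$type == ty]
    expect_gte(length(intersect(planted, found)), length(planted) - 1)
  }
  # n beyond the gene count returns the full ranking
  full <- top_markers(norm[1:30, ], labels, n = 1000)
  expect_identical(sum(full$type == full$type[1]), 30L)
  # identical types: no stable ranking asserted, fold changes near zero
  same <- dense_norm(rep(c(1, 2), each = 300), 20, 30)
  res <- top_markers(same, rep(c("x", "y"), 15), n = 5)
  expect_true(all(abs(res$log2fc) < 0.5))
})
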