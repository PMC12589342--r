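test_that("scenario configurations carry the expected populations", {
  major <- default_config("major13")
  expect_identical(names(major$populations),
                   c("CancerCells", "AT2", "ClubCells", "CiliatedCells",
                     "ECs", "Fibroblasts", "PlasmaCells", "BCells", "TCells",
                     "Neutrophils", "MastCells", "MPs", "pDCs"))
  macro <- default_config("macro6")
  expect_true(all(c("AZU1", "CXCL10", "FABP4", "SELENOP", "SPP1", "STMN1") %in%
                    unlist(macro$populations)))
  mp <- default_config("mp5")
  expect_length(mp$populations, 5L)
  for (g in names(mp$group_proportions))
    expect_equal(sum(mp$group_proportions[[g]]), 1, tolerance = 1e-12)
  expect_error(default_config("major14"), "unknown scenario")
})

test_that("configuration validation rejects broken inputs", {
  expect_error(two_pop_config(pA = 0.6, pA2 = 0.7) |> (\(cfg) {
    cfg$group_proportions$g1 <- c(A = 0.6, B = 0.5)
    validate_sim_config(cfg)
  })(), "sum to")
  cfg <- two_pop_config()
  cfg$populations$B <- c("MKA1", "MKB1")  # MKA1 now in both populations
  expect_error(validate_sim_config(cfg), "more than one population")
  expect_error(sim_config(list(A = "M1", B = "M2"),
                          list(g1 = c(A = 0.5, B = 0.5)),
                          data.frame(sample_id = "s1", group = "g1"),
                          n_genes = 50, nb_dispersion = -1),
               "nb_dispersion")
})

test_that("exact allocation and determinism contracts hold", {
  cfg <- two_pop_config(pA = 0.5, n_cells_per_sample = 50, groups = c("g1", "g1"),
                        exact_proportions = TRUE)
  d <- simulate_dataset(cfg)
  expect_identical(as.vector(table(d$truth$major_type)), c(50L, 50L))
  d2 <- simulate_dataset(cfg)
  expect_identical(as.matrix(d$counts), as.matrix(d2$counts))
  expect_identical(d$truth, d2$truth)
  # different seed changes the draw
  cfg3 <- two_pop_config(pA = 0.5, seed = 99)
  expect_false(identical(simulate_dataset(cfg3)$counts, d$counts))
})

test_that("counts are integer non-negative and truth covers every cell", {
  d <- simulate_dataset(two_pop_config(n_cells_per_sample = 40))
  x <- d$counts@x
  expect_true(all(x >= 0) && all(x == round(x)))
  expect_setequal(d$truth$cell_id, colnames(d$counts))
  expect_identical(anyDuplicated(d$truth$cell_id), 0L)
})

test_that("marker fold-change is realized in the generated means", {
  cfg <- two_pop_config(pA = 0.5, n_cells_per_sample = 1000, fold = 8,
                        groups = c("g1", "g1"), seed = 42)
  d <- simulate_dataset(cfg)
  inA <- d$truth$major_type == "A"
  for (g in c("MKA1", "MKA2")) {
    ratio <- mean(d$counts[g, inA]) / mean(d$counts[g, !inA])
    expect_gte(ratio, 6)
    expect_lte(ratio, 10)
  }
})

test_that("per-group composition converges to the planted proportions", {
  cfg <- default_config("major13", n_cells_per_sample = 1700, n_genes = 300,
                        seed = 11)
  d <- simulate_dataset(cfg)
  for (g in TISSUE_GROUPS) {
    cells <- d$truth$group == g
    freq <- table(factor(d$truth$major_type[cells],
                         levels = names(cfg$populations))) / sum(cells)
    l1 <- sum(abs(as.numeric(freq) - cfg$group_proportions[[g]]))
    expect_lt(l1, 0.05)
  }
})

test_that("non-marker genes have population-independent means", {
  cfg <- default_config("mp5", n_cells_per_sample = 120, n_genes = 400,
                        seed = 5)
  d <- simulate_dataset(cfg)
  markers <- c(unlist(cfg$populations), cfg$shared_markers)
  nonmark <- setdiff(rownames(d$counts), markers)
  a <- d$truth$mp_subtype == "Macrophages"
  b <- d$truth$mp_subtype == "Monocytes"
  pvals <- vapply(nonmark, function(g)
    stats::t.test(d$counts[g, a], d$counts[g, b])$p.value, numeric(1))
  expect_gte(mean(pvals > 0.01, na.rm = TRUE), 0.95)
})

test_that("planted Ro/e matches hand-computed expectations", {
  # identical composition in both groups: ratio 1 everywhere
  flat <- two_pop_config(pA = 0.3, pA2 = 0.3)
  expect_equal(unname(planted_roe(flat)), matrix(1, 2, 2), tolerance = 1e-12)
  # equal group sizes, type A at 0.6 vs 0.2: Ro/e(A, g1) = 0.6 / 0.4
  skew <- two_pop_config(pA = 0.6, pA2 = 0.2)
  expect_equal(planted_roe(skew)["A", "g1"], 1.5, tolerance = 1e-12)
  # scaling every group total leaves the ratio unchanged
  big <- two_pop_config(pA = 0.6, pA2 = 0.2, n_cells_per_sample = 500)
  expect_equal(planted_roe(big), planted_roe(skew), tolerance = 1e-12)
})

test_that("cohort simulation respects the hierarchy and its nullability", {
  d <- simulate_cohort(n_cells_per_sample = 100, n_genes = 400, seed = 3)
  tr <- d$truth
  expect_true(all(is.na(tr$mp_subtype) | tr$major_type == "MPs"))
  expect_true(all(is.na(tr$macro_subtype) |
                    (!is.na(tr$mp_subtype) & tr$mp_subtype == "Macrophages")))
  expect_true(all(!is.na(tr$mp_subtype[tr$major_type == "MPs"])))
  expect_setequal(unique(tr$group), TISSUE_GROUPS)
  # macrophage cells carry markers of all three levels of their path
  mac <- tr$cell_id[!is.na(tr$macro_subtype) & tr$macro_subtype == "Macrophages_SPP1"]
  other <- tr$cell_id[tr$major_type == "TCells"]
  for (g in c("LYZ", "CD68", "SPP1"))
    expect_gt(mean(d$counts[g, mac]), 2 * mean(d$counts[g, other]))
})

test_that("datasets round-trip through the 10x-style text writer", {
  d <- simulate_dataset(two_pop_config(n_cells_per_sample = 30))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  m <- read_tenx(dir)
  expect_equal(as.matrix(m), as.matrix(d$counts))
  expect_identical(colnames(m), colnames(d$counts))
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  expect_identical(truth$cell_id, d$truth$cell_id)
})
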