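test_that("module scores vanish on constant expression and reproduce from seed", {
  flat <- dense_norm(2, 200, 30)
  sc <- module_score(flat, rownames(flat)[1:10], seed = 1)
  expect_equal(unname(sc), rep(0, 30), tolerance = 1e-12)
  noisy <- dense_norm(withr::with_seed(1, rnorm(200 * 30, 2, 0.5)), 200, 30)
  s1 <- module_score(noisy, rownames(noisy)[1:10], seed = 3)
  s2 <- module_score(noisy, rownames(noisy)[1:10], seed = 3)
  expect_identical(s1, s2)
  expect_warning(module_score(noisy, c("g1", "g2", "ghost"), seed = 1),
                 "not in matrix")
  expect_error(suppressWarnings(module_score(noisy, c("no1", "no2"), seed = 1,
                                             set_name = "M9")), "M9")
})

test_that("a planted uniform shift is recovered by the score", {
  # heterogeneous baselines spread genes over the expression bins (controls
  # are drawn per bin, so a one-bin background would be degenerate)
  withr::with_seed(7, {
    base <- runif(400, 0, 4)
    m <- dense_norm(rnorm(400 * 500, mean = rep(base, 500), sd = 0.3),
                    400, 500)
    set_genes <- rownames(m)[seq(10, 400, by = 27)]  # spread over the range
    shifted_cells <- 1:100
    m[set_genes, shifted_cells] <- m[set_genes, shifted_cells] + 2
  })
  sc <- module_score(m, set_genes, seed = 1)
  expect_equal(mean(sc[shifted_cells]) - mean(sc[-shifted_cells]), 2,
               tolerance = 0.1)
  # the background sits near zero (bin-matched controls absorb part of the
  # planted shift through the set genes' raised averages)
  expect_lt(abs(mean(sc[-shifted_cells])), 0.5)
})

test_that("scores are invariant to a global location shift", {
  withr::with_seed(8, m <- dense_norm(rnorm(300 * 100, 2, 0.4), 300, 100))
  sc1 <- module_score(m, rownames(m)[11:25], seed = 2)
  sc2 <- module_score(m + 1.7, rownames(m)[11:25], seed = 2)
  expect_lt(max(abs(mean(sc1) - mean(sc2))), 0.05)
})

test_that("summaries attach the right test and star labels", {
  withr::with_seed(21, {
    # two far-apart groups: t-test, p far below 0.001
    strong <- c(rnorm(100, 0), rnorm(100, 3))
    lab2 <- rep(c("a", "b"), each = 100)
  })
  sm <- summarize_scores(strong, lab2)
  expect_identical(nrow(sm), 2L)
  expect_lt(sm$p_value[1], 1e-3)
  expect_identical(sm$star[1], "***")
  expect_equal(sm$n, c(100, 100))
  # three groups route through one-way ANOVA
  withr::with_seed(22, three <- rnorm(90))
  sm3 <- summarize_scores(three, rep(c("a", "b", "c"), each = 30))
  expect_identical(nrow(sm3), 3L)
  expect_true(all(sm3$star %in% c("ns", "*", "**", "***")))
  # z-scores of the group means across entities; zero variance -> all zero
  expect_equal(sum(sm3$z_score), 0, tolerance = 1e-9)
  sm0 <- summarize_scores(rep(1, 40), rep(c("a", "b"), each = 20))
  expect_equal(sm0$z_score, c(0, 0))
  expect_true(is.na(sm0$p_value[1]))  # constant data cannot be tested
  # under-sized groups are dropped from testing with a warning
  expect_warning(summarize_scores(c(rnorm(20), 1), c(rep(c("a", "b"), 10), "tiny")),
                 "tiny")
})

test_that("star labels track the p-value thresholds", {
  withr::with_seed(30, {
    for (rep in seq_len(40)) {
      x <- rnorm(60, mean = rep(c(0, rnorm(1, 0, 0.8)), each = 30))
      sm <- summarize_scores(x, rep(c("a", "b"), each = 30))
      p <- sm$p_value[1]
      want <- if (p < 0.001) "***" else if (p < 0.01) "**"
              else if (p < 0.05) "*" else "ns"
      expect_identical(sm$star[1], want)
    }
  })
})

test_that("the ANOVA null is calibrated at the nominal level", {
  reps <- 1000
  rejected <- withr::with_seed(99, vapply(seq_len(reps), function(i) {
    sm <- summarize_scores(rnorm(60), rep(c("a", "b", "c"), each = 20))
    sm$p_value[1] < 0.05
  }, logical(1)))
  expect_gte(mean(rejected), 0.03)
  expect_lte(mean(rejected), 0.07)
  expect_gte(mean(!rejected), 0.94)  # "ns" under the null
})

test_that("M1/M2 report recovers the planted polarization ordering", {
  d <- simulate_dataset(default_config("macro6", n_cells_per_sample = 100,
                                       n_genes = 400, seed = 10))
  norm <- normalize_log(d$counts)
  ann <- d$truth
  class(ann) <- c("cell_annotation", "data.frame")
  rep <- m1_m2_report(norm, ann, seed = 1)
  m1 <- rep[rep$set == "M1" & rep$grouping == "macro_subtype", ]
  expect_identical(m1$entity[which.max(m1$mean)], "Macrophages_CXCL10")
  m2 <- rep[rep$set == "M2" & rep$grouping == "macro_subtype", ]
  expect_identical(m2$entity[which.max(m2$mean)], "Macrophages_FABP4")
  expect_setequal(unique(rep$grouping), c("group", "macro_subtype"))
  # a set with no genes in the matrix is an error naming the set
  expect_error(suppressWarnings(
    m1_m2_report(norm, ann, sets = list(EMPTY = c("NOT1", "NOT2")))), "EMPTY")
  # without macrophage labels the report points back to annotation
  bare <- ann; bare$macro_subtype <- NA_character_
  expect_error(m1_m2_report(norm, bare), "annotate")
})

test_that("GMT collections round-trip", {
  sets <- list(S1 = c("A", "B", "C"), S2 = c("D", "E"))
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, tmp)
  expect_identical(read_gmt(tmp), sets)
  pol <- default_polarization_sets()
  expect_setequal(names(pol), c("M1", "M2"))
  expect_true("CXCL10" %in% pol$M1 && "FABP4" %in% pol$M2)
})
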