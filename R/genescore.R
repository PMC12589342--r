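# Gene-set module scoring and group comparisons.
#
# Per-cell module score: mean expression of the set genes minus the mean of
# control genes drawn from matching average-expression bins, the dominant
# convention for single-cell signature ("module") scores. Summaries attach
# z-scores across entities and the t-test / one-way ANOVA comparison with the
# usual significance stars.

#' Per-cell module score with expression-matched controls
#'
#' Genes are ranked by average expression across cells and cut into `n_bins`
#' bins; each set gene contributes `n_ctrl` control genes sampled from its
#' bin. The score of a cell is the mean over set genes minus the mean over
#' the pooled control genes, making the score robust to global expression
#' shifts. Reproducible from `seed`.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param genes Character vector: the gene set. Genes absent from the matrix
#'   are dropped with a warning; an empty intersection is an error.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_ctrl Controls sampled per set gene (default 50).
#' @param seed Integer seed for control sampling.
#' @param set_name Used in error messages.
#' @return Numeric per-cell scores, named by cell.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 50, seed = 1L,
                         set_name = "gene set") {
  .assert(length(genes) > 0, "empty gene set")
  .assert(!anyDuplicated(genes), sprintf("%s contains duplicate genes", set_name))
  present <- intersect(genes, rownames(norm))
  if (length(present) < length(genes))
    warning(sprintf("%s: %d gene(s) not in matrix, dropped", set_name,
                    length(genes) - length(present)))
  .assert(length(present) > 0,
          sprintf("no genes of %s are present in the matrix", set_name))
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(avg))
  # equal-frequency bins on the average-expression ranking
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  names(bin) <- rownames(norm)
  ctrl <- withr::with_seed(seed, {
    unique(unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, min(n_ctrl, length(pool)))
    }), use.names = FALSE))
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

.star_label <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*" else "ns"
  }, character(1))
}

#' Summarize scores by group with a significance test
#'
#' Per group: mean, standard deviation, size, and the z-score of the group
#' mean across groups (zero-variance means give z = 0). Two groups are
#' compared with a t-test (Welch by default, Student via
#' `var_equal = TRUE`); three or more with a classic one-way ANOVA. Stars
#' follow the usual thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' else `ns` (a p of exactly 0.05 is `ns`). Groups with fewer than 2 cells
#' are excluded from testing with a warning.
#'
#' @param scores Numeric per-cell scores.
#' @param labels Grouping vector, same length as `scores`.
#' @param var_equal Use the equal-variance (Student) t-test for two groups
#'   and is passed to the ANOVA as well.
#' @return A `score_summary` data frame: `entity`, `mean`, `sd`, `n`,
#'   `z_score`, `p_value`, `star` (the test p is shared across rows).
#' @export
summarize_scores <- function(scores, labels, var_equal = FALSE) {
  .assert(length(scores) == length(labels),
          "scores and labels must have the same length")
  labels <- as.character(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_by <- table(labels)
  small <- names(n_by)[n_by < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with n < 2 from testing: %s",
                    paste(small, collapse = ", ")))
    keep <- !(labels %in% small)
    scores <- scores[keep]; labels <- labels[keep]
  }
  groups <- sort(unique(labels))
  .assert(length(groups) >= 2, "summarize_scores needs at least 2 groups")
  mean_by <- vapply(groups, function(g) mean(scores[labels == g]), numeric(1))
  sd_by <- vapply(groups, function(g) sd(scores[labels == g]), numeric(1))
  n_by <- vapply(groups, function(g) sum(labels == g), numeric(1))
  z <- if (sd(mean_by) < 1e-12) rep(0, length(mean_by)) else
    as.numeric(scale(mean_by))
  # degenerate (constant) data cannot be tested; report a missing p
  p <- tryCatch(
    if (length(groups) == 2) {
      t.test(scores[labels == groups[1]], scores[labels == groups[2]],
             var.equal = var_equal)$p.value
    } else {
      oneway.test(scores ~ factor(labels), var.equal = TRUE)$p.value
    },
    error = function(e) NA_real_)
  out <- data.frame(entity = groups, mean = unname(mean_by),
                    sd = unname(sd_by), n = unname(n_by), z_score = z,
                    p_value = p, star = .star_label(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_summary", "data.frame")
  out
}

#' M1/M2 polarization report over tissue groups and macrophage states
#'
#' Scores the M1 and M2 programs on all cells carrying a six-gene macrophage
#' state label and summarizes each program by tissue group and by macrophage
#' subtype.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param annotation A `cell_annotation` with `macro_subtype` filled for the
#'   macrophage cells.
#' @param sets Named list of gene sets; defaults to the packaged M1/M2
#'   programs.
#' @param n_bins,n_ctrl,seed Passed to [module_score()].
#' @return Tidy data frame: `set`, `grouping` (`"group"` or
#'   `"macro_subtype"`), plus the [summarize_scores()] columns.
#' @export
m1_m2_report <- function(norm, annotation, sets = default_polarization_sets(),
                         n_bins = 25, n_ctrl = 50, seed = 1L) {
  .assert("macro_subtype" %in% names(annotation),
          "annotation lacks macro_subtype; run annotate_hierarchy() first")
  mac <- annotation[!is.na(annotation$macro_subtype), , drop = FALSE]
  .assert(nrow(mac) > 0,
          "no cells with macrophage subtype labels; run annotate_hierarchy() first")
  sub <- norm[, mac$cell_id, drop = FALSE]
  out <- list()
  for (set_name in names(sets)) {
    sc <- module_score(sub, sets[[set_name]], n_bins = n_bins,
                       n_ctrl = n_ctrl, seed = seed, set_name = set_name)
    for (grouping in c("group", "macro_subtype")) {
      sm <- summarize_scores(sc, mac[[grouping]])
      sm <- cbind(set = set_name, grouping = grouping, sm)
      out[[length(out) + 1L]] <- sm
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
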