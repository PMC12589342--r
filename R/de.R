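# Differential expression and over-representation analysis.

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test (exact for small groups
#' without ties, normal approximation with tie correction otherwise) and the
#' log2 fold change of pseudocounted group means,
#' `log2((mean_a + c) / (mean_b + c))`. Group means are taken on the
#' normalized expression scale (the log transform is inverted first, the
#' usual fold-change convention), while the rank test uses the values as
#' given. Benjamini-Hochberg q-values are attached.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param cells_a,cells_b Column indices or names of the two groups.
#' @param pseudocount Pseudocount `c` on the normalized scale (default 1).
#' @return Data frame `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`,
#'   `direction` (filled by [volcano_classify()], `NA` here).
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, pseudocount = 1) {
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  .assert(ncol(a) > 0 && ncol(b) > 0, "both cell groups must be non-empty")
  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  p <- vapply(seq_len(nrow(a)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
    suppressWarnings(wilcox.test(xa, xb)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  data.frame(gene = rownames(norm), mean_a = mean_a, mean_b = mean_b,
             log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)),
             p = p, q = bh_adjust(p), direction = NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; order-preserving and bounded by 1.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  .assert(is.numeric(pvals) && length(pvals) > 0 && !anyNA(pvals),
          "pvals must be numeric and non-missing")
  .assert(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Classify genes into volcano-plot quadrants
#'
#' `up` when `log2fc >= lfc_cut` and `q < q_cut`; `down` when
#' `log2fc <= -lfc_cut` and `q < q_cut`; otherwise `ns`.
#'
#' @param results Output of [wilcoxon_de()].
#' @param lfc_cut Absolute log2 fold-change cutoff (default 1).
#' @param q_cut q-value cutoff (default 0.05).
#' @return `results` with `direction` filled.
#' @export
volcano_classify <- function(results, lfc_cut = 1, q_cut = 0.05) {
  .assert(all(c("log2fc", "q") %in% names(results)),
          "results must come from wilcoxon_de()")
  results$direction <- ifelse(
    results$log2fc >= lfc_cut & results$q < q_cut, "up",
    ifelse(results$log2fc <= -lfc_cut & results$q < q_cut, "down", "ns"))
  results
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the overlap between a query gene list
#' and each set of a collection, within a fixed gene universe. Sets are
#' intersected with the universe; the query must be contained in it.
#'
#' @param query Character vector of query genes (non-empty, within universe).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the gene universe.
#' @return Data frame sorted by p: `set`, `overlap` (k), `set_size` (K within
#'   universe), `query_size` (n), `universe_size` (N), `p`, `q`.
#' @export
hypergeom_ora <- function(query, collection, universe) {
  .assert(length(query) > 0, "empty query gene list")
  .assert(length(universe) > 0, "empty gene universe")
  .assert(!anyDuplicated(universe), "universe contains duplicate genes")
  query <- unique(query)
  outside <- setdiff(query, universe)
  .assert(length(outside) == 0,
          sprintf("query gene(s) outside the universe: %s",
                  paste(utils::head(outside, 5), collapse = ", ")))
  .assert(is.list(collection) && length(collection) > 0 &&
            !is.null(names(collection)), "collection must be a named list")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
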