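# Ligand-receptor interaction scoring with a label-permutation null.
#
# Scoring convention (mean-expression product with min-over-complex, the
# CellPhoneDB family of statistics): the score of a pair is the product of
# the sender-side ligand mean and the receiver-side receptor mean, where a
# multi-gene complex contributes the minimum of its members' means.

.complex_mean <- function(means, genes) {
  min(means[genes])
}

#' Score one ligand-receptor pair between sender and receiver cells
#'
#' `score = min over ligand-complex genes of the sender mean  x  min over
#' receptor-complex genes of the receiver mean`. A pair with any gene absent
#' from the matrix returns `NA` with a warning (the pair is "skipped").
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param sender_cells,receiver_cells Column indices or names; both non-empty.
#' @param pair List or one-row data frame with `pair`, `ligand_genes`,
#'   `receptor_genes` (character vectors, complexes allowed).
#' @return A single non-negative score, or `NA` when skipped.
#' @export
lr_score <- function(norm, sender_cells, receiver_cells, pair) {
  .assert(length(sender_cells) > 0 && length(receiver_cells) > 0,
          "sender and receiver cell sets must be non-empty")
  lig <- unlist(pair$ligand_genes, use.names = FALSE)
  rec <- unlist(pair$receptor_genes, use.names = FALSE)
  missing <- setdiff(c(lig, rec), rownames(norm))
  if (length(missing)) {
    warning(sprintf("pair %s skipped: gene(s) absent: %s",
                    pair$pair %||% "?", paste(missing, collapse = ", ")))
    return(NA_real_)
  }
  s_mean <- Matrix::rowMeans(norm[lig, sender_cells, drop = FALSE])
  r_mean <- Matrix::rowMeans(norm[rec, receiver_cells, drop = FALSE])
  .complex_mean(s_mean, lig) * .complex_mean(r_mean, rec)
}

#' Permutation test for ligand-receptor scores
#'
#' Observed scores are compared with a null built by jointly shuffling the
#' sender/receiver labels across the two populations; the p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`, bounded below by
#' `1 / (n_perm + 1)`. Pairs with absent genes are skipped with a warning.
#' Reproducible from `seed`.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param sender_cells,receiver_cells Column names or indices of the two
#'   populations (disjoint).
#' @param pairs Data frame from [default_lr_pairs()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Data frame `pair`, `score`, `p_value`, `n_perm` (skipped pairs are
#'   omitted).
#' @export
permutation_test <- function(norm, sender_cells, receiver_cells, pairs,
                             n_perm = 999, seed = 1L) {
  .assert(n_perm >= 1, "n_perm must be >= 1")
  .assert(length(sender_cells) > 0 && length(receiver_cells) > 0,
          "sender and receiver cell sets must be non-empty")
  if (is.numeric(sender_cells)) sender_cells <- colnames(norm)[sender_cells]
  if (is.numeric(receiver_cells)) receiver_cells <- colnames(norm)[receiver_cells]
  usable <- vapply(seq_len(nrow(pairs)), function(i) {
    genes <- c(unlist(pairs$ligand_genes[[i]]), unlist(pairs$receptor_genes[[i]]))
    ok <- all(genes %in% rownames(norm))
    if (!ok) warning(sprintf("pair %s skipped: gene(s) absent",
                             pairs$pair[[i]]))
    ok
  }, logical(1))
  pairs <- pairs[usable, , drop = FALSE]
  .assert(nrow(pairs) > 0, "no scorable pairs (all genes absent)")
  need <- unique(c(unlist(pairs$ligand_genes), unlist(pairs$receptor_genes)))
  sub <- as.matrix(norm[need, c(sender_cells, receiver_cells), drop = FALSE])
  n_s <- length(sender_cells)
  n_all <- ncol(sub)
  score_for <- function(s_idx, r_idx) {
    s_mean <- rowMeans(sub[, s_idx, drop = FALSE])
    r_mean <- rowMeans(sub[, r_idx, drop = FALSE])
    vapply(seq_len(nrow(pairs)), function(i) {
      lig <- unlist(pairs$ligand_genes[[i]])
      rec <- unlist(pairs$receptor_genes[[i]])
      min(s_mean[lig]) * min(r_mean[rec])
    }, numeric(1))
  }
  observed <- score_for(seq_len(n_s), (n_s + 1L):n_all)
  exceed <- integer(nrow(pairs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n_all)
      perm_scores <- score_for(perm[seq_len(n_s)], perm[(n_s + 1L):n_all])
      exceed <- exceed + (perm_scores >= observed)
    }
  })
  data.frame(pair = pairs$pair, score = observed,
             p_value = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
             stringsAsFactors = FALSE, row.names = NULL)
}
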