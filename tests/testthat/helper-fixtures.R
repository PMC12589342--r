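# Shared fixtures and independent oracles used across the suite.

# --- tiny simulation configs -------------------------------------------------

two_pop_config <- function(pA = 0.5, n_cells_per_sample = 50, fold = 8,
                           seed = 1, groups = c("g1", "g2"),
                           pA2 = pA, n_genes = 60, ...) {
  samples <- data.frame(sample_id = c("s1", "s2"), group = groups,
                        stringsAsFactors = FALSE)
  props <- list(setNames(c(pA, 1 - pA), c("A", "B")),
                setNames(c(pA2, 1 - pA2), c("A", "B")))
  names(props) <- unique(groups)
  if (length(unique(groups)) == 1) props <- props[1]
  sim_config(populations = list(A = c("MKA1", "MKA2", "MKA3", "MKA4"),
                                B = c("MKB1", "MKB2", "MKB3", "MKB4")),
             group_proportions = props, samples = samples,
             n_genes = n_genes, n_cells_per_sample = n_cells_per_sample,
             marker_fold = fold, seed = seed, ...)
}

# dense log-scale matrix with named dims, convenient for scoring tests
dense_norm <- function(values, n_genes, n_cells, gene_prefix = "g") {
  m <- matrix(values, nrow = n_genes, ncol = n_cells)
  dimnames(m) <- list(paste0(gene_prefix, seq_len(n_genes)),
                      paste0("c", seq_len(n_cells)))
  m
}

# --- independent oracles -----------------------------------------------------

# Exact two-sided Wilcoxon rank-sum p by enumerating all group assignments.
wilcox_enum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_along(a)])
  combos <- utils::combn(length(pooled), length(a))
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Upper-tail hypergeometric p by enumerating every possible query subset.
hyper_enum_p <- function(N, K, n, k) {
  set <- seq_len(K)
  combos <- utils::combn(N, n)
  overlaps <- apply(combos, 2, function(q) sum(q <= K))
  mean(overlaps >= k)
}

# Benjamini-Hochberg step-up written out longhand.
bh_manual <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}
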