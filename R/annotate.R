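# Marker-driven hierarchical cell-type annotation.
#
# normalize -> cluster -> score clusters against a marker reference -> assign
# each cluster its argmax type, run at three levels: all cells against the
# 13-type major reference, the MPs subset against the 5-subtype reference, and
# the macrophage subset against the six-gene classification.

#' Library-size normalize and log-transform counts
#'
#' Scales every cell to `target_sum` total counts, then applies a natural
#' `log(1 + x)` transform. Cells with zero total counts cannot be scaled and
#' are dropped with a warning.
#'
#' @param counts Genes-by-cells sparse (or dense) non-negative count matrix
#'   with dimnames.
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A genes-by-cells `dgCMatrix` of log-normalized values.
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(2, 2),
#'                           dims = c(2, 1),
#'                           dimnames = list(c("g1", "g2"), "c1"))
#' normalize_log(m, target_sum = 4)  # both entries become log(3)
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  .assert(target_sum > 0, "target_sum must be positive")
  counts <- methods::as(counts, "CsparseMatrix")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero cell(s): %s", sum(zero),
                    paste(utils::head(colnames(counts)[zero], 5),
                          collapse = ", ")))
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  .assert(ncol(counts) > 0, "no cells with nonzero counts remain")
  norm <- counts %*% Matrix::Diagonal(x = target_sum / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  methods::as(norm, "CsparseMatrix")
}

# Row-wise variance of a sparse matrix without densifying.
.row_vars <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

# Highly variable genes by mean-binned normalized dispersion: genes are
# binned by mean expression and ranked by the z-score of var/mean within
# their bin, so bimodal markers outrank merely highly expressed genes.
.select_hvg <- function(m, n_hvg, n_bins = 20) {
  vars <- .row_vars(m)
  mu <- Matrix::rowMeans(m)
  informative <- which(vars > 1e-12)
  if (length(informative) <= n_hvg) return(informative)
  disp <- vars[informative] / pmax(mu[informative], 1e-9)
  qs <- unique(quantile(mu[informative], probs = seq(0, 1, 1 / n_bins)))
  bin <- if (length(qs) > 2)
    cut(mu[informative], breaks = qs, include.lowest = TRUE)
  else factor(rep(1, length(informative)))
  zdisp <- ave(disp, bin,
               FUN = function(x) (x - mean(x)) / max(sd(x), 1e-9))
  informative[order(zdisp, decreasing = TRUE)[seq_len(n_hvg)]]
}

# Exact k-nearest-neighbour indices on a cells x dims score matrix, computed
# in chunks to bound memory.
.knn_indices <- function(scores, k, chunk = 1000L) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  sq <- rowSums(scores^2)
  nn <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(scores[idx, , drop = FALSE],
                                                   scores)
    for (r in seq_along(idx)) {
      ord <- order(d2[r, ])
      nn[idx[r], ] <- setdiff(ord, idx[r])[seq_len(k)]
    }
  }
  nn
}

#' Cluster cells by graph community detection on principal components
#'
#' Selects highly variable genes, z-scales them, reduces to principal
#' components, builds an exact k-nearest-neighbour graph and partitions it
#' with Louvain community detection at the given resolution. A k-means
#' fallback (`method = "kmeans"`, where `resolution` is taken as the number
#' of centers) is available. Deterministic for a fixed seed.
#'
#' @param norm Log-normalized genes-by-cells matrix from [normalize_log()].
#' @param n_components Number of principal components (reduced with a warning
#'   if the data cannot support it).
#' @param resolution Louvain resolution parameter, or the number of clusters
#'   when `method = "kmeans"`.
#' @param seed Integer seed.
#' @param method `"louvain"` (default) or `"kmeans"`.
#' @param k_neighbors Neighbourhood size of the kNN graph.
#' @param n_hvg Number of highly variable genes retained before the PCA.
#' @return Integer cluster labels (1-based), named by cell.
#' @export
cluster_cells <- function(norm, n_components = 20, resolution = 1, seed = 1L,
                          method = c("louvain", "kmeans"), k_neighbors = 15,
                          n_hvg = 500) {
  method <- match.arg(method)
  .assert(ncol(norm) >= 2, "clustering needs at least 2 cells")
  # canonical internal cell order makes the partition invariant to the
  # order cells arrive in (graph community detection is order-sensitive)
  if (!is.null(colnames(norm)) && !anyDuplicated(colnames(norm))) {
    orig <- colnames(norm)
    norm <- norm[, order(orig), drop = FALSE]
    restore <- match(orig, colnames(norm))
  } else {
    restore <- seq_len(ncol(norm))
  }
  vars <- .row_vars(norm)
  if (all(vars < 1e-12)) {
    # degenerate input: all cells identical
    return(setNames(rep(1L, ncol(norm)), colnames(norm))[restore])
  }
  hvg <- .select_hvg(norm, n_hvg)
  x <- t(as.matrix(norm[hvg, , drop = FALSE]))
  x <- scale(x)
  x[, attr(x, "scaled:scale") < 1e-12] <- 0
  x[x > 10] <- 10  # cap extreme standardized values
  max_pc <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_pc) {
    warning(sprintf("reducing n_components from %d to %d", n_components,
                    max_pc))
    n_components <- max_pc
  }
  withr::with_seed(seed, {
    pcs <- prcomp(x, center = FALSE, scale. = FALSE,
                  rank. = n_components)$x
    if (method == "kmeans") {
      centers <- max(1L, round(resolution))
      labels <- kmeans(pcs, centers = centers, nstart = 10,
                       iter.max = 100)$cluster
    } else {
      nn <- .knn_indices(pcs, k_neighbors)
      edges <- cbind(rep(seq_len(nrow(nn)), ncol(nn)), as.vector(nn))
      g <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                        directed = FALSE))
      comm <- igraph::cluster_louvain(g, resolution = resolution)
      labels <- igraph::membership(comm)
    }
    labels <- as.integer(labels)
  })
  setNames(labels, colnames(norm))[restore]
}

#' Score clusters against a marker reference
#'
#' For every (cluster, type) pair: the mean, over the type's present marker
#' genes, of the z-scored (across all cells) mean expression in the cluster.
#' Genes with zero variance get a z-score of 0. Reference markers missing from
#' the matrix are dropped with a warning; a type losing all its markers is an
#' error.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param labels Cluster labels per cell (same order as columns).
#' @param ref A `marker_reference`.
#' @return Numeric matrix clusters x types of marker scores.
#' @export
score_cluster_types <- function(norm, labels, ref) {
  .assert(inherits(ref, "marker_reference"), "ref must be a marker_reference")
  .assert(length(labels) == ncol(norm),
          "labels must have one entry per cell")
  all_markers <- unique(unlist(ref$entries, use.names = FALSE))
  present <- intersect(all_markers, rownames(norm))
  missing <- setdiff(all_markers, present)
  if (length(missing))
    warning(sprintf("%d marker gene(s) absent from the matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 8), collapse = ", ")))
  lost <- names(ref$entries)[vapply(ref$entries, function(g)
    length(intersect(g, present)) == 0, logical(1))]
  .assert(length(lost) == 0,
          sprintf("no marker genes present for type(s): %s",
                  paste(lost, collapse = ", ")))
  x <- as.matrix(norm[present, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  z <- (x - mu) / ifelse(sdv < 1e-12, 1, sdv)
  z[sdv < 1e-12, ] <- 0
  clusters <- sort(unique(labels))
  cl_means <- vapply(clusters, function(cl)
    rowMeans(z[, labels == cl, drop = FALSE]), numeric(nrow(z)))
  if (is.null(dim(cl_means))) cl_means <- matrix(cl_means, nrow = 1)
  rownames(cl_means) <- present
  scores <- vapply(ref$entries, function(genes)
    colMeans(cl_means[intersect(genes, present), , drop = FALSE]),
    numeric(length(clusters)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = 1, dimnames = list(NULL, names(ref$entries)))
  rownames(scores) <- as.character(clusters)
  scores
}

#' Assign each cluster the argmax-scoring type
#'
#' Ties are broken lexicographically by type name and flagged.
#'
#' @param score_table Clusters x types score matrix from
#'   [score_cluster_types()].
#' @return Data frame with columns `cluster`, `type`, `tie`.
#' @export
assign_types <- function(score_table) {
  .assert(is.matrix(score_table) && !anyNA(score_table),
          "score table must be a complete numeric matrix")
  types <- colnames(score_table)[order(colnames(score_table))]
  ordered <- score_table[, types, drop = FALSE]
  assigned <- apply(ordered, 1, function(row) types[which.max(row)])
  tie <- apply(ordered, 1, function(row) sum(row == max(row)) > 1)
  data.frame(cluster = rownames(score_table), type = unname(assigned),
             tie = unname(tie), stringsAsFactors = FALSE)
}

.annotate_level <- function(norm, ref, resolution, seed, ...) {
  labels <- cluster_cells(norm, resolution = resolution, seed = seed, ...)
  scores <- score_cluster_types(norm, labels, ref)
  mapping <- assign_types(scores)
  list(cluster = labels,
       type = setNames(mapping$type, mapping$cluster)[as.character(labels)])
}

#' Hierarchical cell-type annotation
#'
#' Runs normalize, cluster, score, assign at the major level on all cells;
#' repeats on the MPs subset with the MP reference; repeats on the macrophage
#' subset with the six-gene macrophage reference. Empty subsets skip their
#' level with a warning. Subtype columns respect the nullability rules:
#' `mp_subtype` is non-missing only for `MPs` cells and `macro_subtype` only
#' for `Macrophages` MP cells.
#'
#' @param counts Genes-by-cells raw count matrix.
#' @param metadata Data frame with columns `cell_id`, `sample_id`, `group`
#'   covering every cell.
#' @param refs List with `marker_reference`s named `major`, `mp`, `macro`;
#'   defaults to the packaged references.
#' @param target_sum Normalization target.
#' @param resolution Louvain resolution used at every level.
#' @param seed Integer seed.
#' @param start_level First level to annotate: `"major"` (default, full
#'   hierarchy), `"mp"` (the data are already an MPs subset; all cells get
#'   `major_type = "MPs"`), or `"macro"` (a macrophage subset). Marker-driven
#'   typing cannot identify a level on which the data do not vary, so a
#'   dataset that is entirely one ancestor type must enter at its own level.
#' @param ... Further arguments to [cluster_cells()].
#' @return A `cell_annotation` data frame: `cell_id`, `sample_id`, `group`,
#'   `cluster_id` (cluster at `start_level`), `major_type`, `mp_subtype`,
#'   `macro_subtype`.
#' @export
annotate_hierarchy <- function(counts, metadata,
                               refs = list(major = default_marker_reference("major"),
                                           mp = default_marker_reference("mp"),
                                           macro = default_marker_reference("macro")),
                               target_sum = 1e4, resolution = 1.5, seed = 1L,
                               start_level = c("major", "mp", "macro"), ...) {
  start_level <- match.arg(start_level)
  .assert(all(c("cell_id", "sample_id", "group") %in% names(metadata)),
          "metadata needs columns cell_id, sample_id, group")
  .assert(all(colnames(counts) %in% metadata$cell_id),
          "metadata must cover every cell in the count matrix")
  norm <- normalize_log(counts, target_sum)
  meta <- metadata[match(colnames(norm), metadata$cell_id), , drop = FALSE]
  ann <- data.frame(cell_id = colnames(norm), sample_id = meta$sample_id,
                    group = meta$group, cluster_id = NA_integer_,
                    major_type = NA_character_, mp_subtype = NA_character_,
                    macro_subtype = NA_character_, stringsAsFactors = FALSE)
  if (start_level == "major") {
    major <- .annotate_level(norm, refs$major, resolution, seed, ...)
    ann$cluster_id <- as.integer(major$cluster)
    ann$major_type <- unname(major$type)
    mp_cells <- ann$cell_id[ann$major_type == "MPs"]
  } else {
    ann$major_type <- "MPs"
    mp_cells <- if (start_level == "mp") ann$cell_id else character()
  }
  if (start_level %in% c("major", "mp")) {
    if (length(mp_cells) >= 2) {
      sub <- .annotate_level(norm[, mp_cells, drop = FALSE], refs$mp,
                             resolution, seed, ...)
      if (start_level == "mp") ann$cluster_id <- as.integer(sub$cluster)
      ann$mp_subtype[match(mp_cells, ann$cell_id)] <- unname(sub$type)
      mac_cells <- mp_cells[sub$type == "Macrophages"]
    } else {
      if (start_level == "major")
        warning("MPs subset too small; MP and macrophage levels skipped")
      mac_cells <- character()
    }
  } else {
    ann$mp_subtype <- "Macrophages"
    mac_cells <- ann$cell_id
  }
  if (length(mac_cells) >= 2) {
    mac <- .annotate_level(norm[, mac_cells, drop = FALSE], refs$macro,
                           resolution, seed, ...)
    if (start_level == "macro") ann$cluster_id <- as.integer(mac$cluster)
    ann$macro_subtype[match(mac_cells, ann$cell_id)] <- unname(mac$type)
  } else if (start_level != "macro" && length(mp_cells) >= 2) {
    warning("macrophage subset too small; six-gene level skipped")
  }
  class(ann) <- c("cell_annotation", "data.frame")
  ann
}

#' Rank marker genes per assigned type
#'
#' One-vs-rest log2 fold changes on the normalized scale (with pseudocount)
#' and two-sided Wilcoxon rank-sum p-values, returning the top `n` genes per
#' type by fold change.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param labels Type labels per cell (at least 2 distinct types).
#' @param n Top genes per type; values above the gene count return the full
#'   ranking.
#' @param pseudocount Added to both means before the ratio.
#' @return Data frame `type`, `gene`, `rank`, `log2fc`, `p_value`, `q_value`.
#' @export
top_markers <- function(norm, labels, n = 30, pseudocount = 1) {
  .assert(length(labels) == ncol(norm), "labels must match the cells")
  types <- sort(unique(as.character(labels)))
  .assert(length(types) >= 2, "top_markers needs at least 2 types")
  n <- min(n, nrow(norm))
  out <- lapply(types, function(ty) {
    de <- wilcoxon_de(norm, which(labels == ty), which(labels != ty),
                      pseudocount = pseudocount)
    de <- de[order(-de$log2fc), , drop = FALSE][seq_len(n), , drop = FALSE]
    data.frame(type = ty, gene = de$gene, rank = seq_len(n),
               log2fc = de$log2fc, p_value = de$p, q_value = de$q,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
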