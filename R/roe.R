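# Observed-over-expected (Ro/e) tissue-preference statistics.
#
# Expected counts come from the chi-squared contingency expectation
# E(i,j) = row_i * col_j / N; the ratio R = O/E measures the enrichment
# tendency of a cell type in a tissue group, with R > 1 read as preference.

#' Cross-tabulate cells into an observed count table
#'
#' Rows are cell types, columns tissue groups. Cells with a missing type or
#' group are excluded, with a message reporting the count. Levels present in
#' the data are retained even when their total is zero.
#'
#' @param annotation A `cell_annotation` (or any data frame).
#' @param type_field Column holding the cell type (e.g. `"major_type"`,
#'   `"mp_subtype"`, `"macro_subtype"`).
#' @param group_field Column holding the tissue group.
#' @return An integer matrix types x groups.
#' @export
contingency <- function(annotation, type_field = "major_type",
                        group_field = "group") {
  .assert(is.data.frame(annotation) && nrow(annotation) > 0,
          "annotation must be a non-empty data frame")
  .assert(all(c(type_field, group_field) %in% names(annotation)),
          sprintf("annotation lacks column(s) %s / %s", type_field, group_field))
  ty <- as.character(annotation[[type_field]])
  gr <- as.character(annotation[[group_field]])
  keep <- !is.na(ty) & !is.na(gr)
  if (any(!keep))
    message(sprintf("contingency: excluding %d cell(s) with missing %s/%s",
                    sum(!keep), type_field, group_field))
  .assert(any(keep), "no cells with complete type and group labels")
  tab <- table(type = ty[keep], group = gr[keep])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Compute the Ro/e table from observed counts
#'
#' Expected counts use the chi-squared contingency formula
#' `E(i,j) = row_total_i * col_total_j / N`; the ratio is `O / E`
#' elementwise. Entries whose row or column total is zero have an undefined
#' ratio and are reported as `NA`, never as zero. A global chi-squared test
#' p-value is attached for context.
#'
#' @param observed Non-negative integer matrix types x groups.
#' @return An object of class `roe_table`: list with `observed`, `expected`,
#'   `roe`, `N`, `chisq_p`.
#' @examples
#' rt <- roe(matrix(c(10, 40, 30, 20), 2,
#'           dimnames = list(c("A", "B"), c("g1", "g2"))))
#' rt$roe
#' @export
roe <- function(observed) {
  .assert(is.matrix(observed) && is.numeric(observed),
          "observed must be a numeric matrix")
  .assert(all(observed >= 0) && all(observed == round(observed)),
          "observed must contain non-negative integer counts")
  N <- sum(observed)
  .assert(N > 0, "observed table is empty (N = 0)")
  row_tot <- rowSums(observed)
  col_tot <- colSums(observed)
  expected <- outer(row_tot, col_tot) / N
  ratio <- observed / expected
  undefined <- outer(row_tot == 0, col_tot == 0, `|`)
  ratio[undefined] <- NA_real_
  chisq_p <- if (all(row_tot > 0) && all(col_tot > 0) &&
                 nrow(observed) > 1 && ncol(observed) > 1) {
    suppressWarnings(chisq.test(observed)$p.value)
  } else NA_real_
  structure(list(observed = observed, expected = expected, roe = ratio,
                 N = N, chisq_p = chisq_p), class = "roe_table")
}

#' Call tissue preferences from a Ro/e table
#'
#' A (type, group) pair is preferred when its ratio strictly exceeds the
#' threshold (default 1, so a ratio of exactly 1 is not a preference).
#' Undefined ratios stay missing.
#'
#' @param roe_table A `roe_table` from [roe()].
#' @param threshold Strict preference threshold on the ratio.
#' @return List with `preferred` (logical matrix) and `long` (data frame
#'   `type`, `group`, `observed`, `expected`, `roe`, `preferred`, sorted by
#'   ratio descending, undefined entries last).
#' @export
preference_calls <- function(roe_table, threshold = 1) {
  .assert(inherits(roe_table, "roe_table"), "need a roe_table from roe()")
  preferred <- roe_table$roe > threshold
  long <- data.frame(
    type = rep(rownames(roe_table$roe), ncol(roe_table$roe)),
    group = rep(colnames(roe_table$roe), each = nrow(roe_table$roe)),
    observed = as.vector(roe_table$observed),
    expected = as.vector(roe_table$expected),
    roe = as.vector(roe_table$roe),
    preferred = as.vector(preferred), stringsAsFactors = FALSE)
  long <- long[order(-long$roe, long$type, long$group, na.last = TRUE), ,
               drop = FALSE]
  rownames(long) <- NULL
  list(preferred = preferred, long = long)
}

#' @export
print.roe_table <- function(x, digits = 3, ...) {
  cat(sprintf("roe_table: %d types x %d groups, N = %d cells\n",
              nrow(x$roe), ncol(x$roe), x$N))
  print(round(x$roe, digits))
  if (!is.na(x$chisq_p))
    cat(sprintf("global chi-squared p = %.3g\n", x$chisq_p))
  invisible(x)
}

#' Ro/e directly from an annotation
#'
#' Convenience wrapper: [contingency()] then [roe()]. `per_sample = TRUE`
#' averages per-sample Ro/e tables instead of pooling cells across samples of
#' a group.
#'
#' @inheritParams contingency
#' @param per_sample Average sample-level tables instead of pooling.
#' @param sample_field Sample column used when `per_sample = TRUE`.
#' @return A `roe_table`; when `per_sample = TRUE` its `roe` is the average
#'   ratio and `observed`/`expected` are pooled for reference.
#' @export
roe_from_annotation <- function(annotation, type_field = "major_type",
                                group_field = "group", per_sample = FALSE,
                                sample_field = "sample_id") {
  pooled <- roe(contingency(annotation, type_field, group_field))
  if (!per_sample) return(pooled)
  sample_groups <- unique(annotation[, c(sample_field, group_field)])
  per <- contingency(annotation, type_field, sample_field)
  rt <- roe(per)
  grp_of <- setNames(as.character(sample_groups[[group_field]]),
                     as.character(sample_groups[[sample_field]]))
  groups <- unique(grp_of[colnames(rt$roe)])
  avg <- vapply(groups, function(g)
    rowMeans(rt$roe[, grp_of[colnames(rt$roe)] == g, drop = FALSE],
             na.rm = TRUE), numeric(nrow(rt$roe)))
  pooled$roe <- avg
  pooled
}
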