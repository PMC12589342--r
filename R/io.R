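# Readers/writers for the plain-text formats the pipeline exchanges:
# MatrixMarket triplet counts with features/barcodes side files, headered TSV,
# and GMT gene-set collections.

#' Write a dataset as 10x-style text files
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer), `features.tsv`,
#' `barcodes.tsv`, and -- for synthetic datasets -- `truth.tsv` with the true
#' per-cell labels.
#'
#' @param dataset A `tme_dataset` from [simulate_dataset()] /
#'   [simulate_cohort()], or a bare genes-by-cells sparse count matrix.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  counts <- if (inherits(dataset, "tme_dataset")) dataset$counts else dataset
  .assert(inherits(counts, "sparseMatrix"), "counts must be a sparse matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- Matrix::summary(counts)
  con <- file(file.path(dir, "matrix.mtx"), open = "wb")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(trip))),
             con, sep = "\n")
  close(con)
  data.table::fwrite(data.table::data.table(i = trip$i, j = trip$j,
                                            x = as.integer(trip$x)),
                     file.path(dir, "matrix.mtx"), sep = " ",
                     col.names = FALSE, append = TRUE, eol = "\n")
  data.table::fwrite(data.table::data.table(id = rownames(counts),
                                            name = rownames(counts),
                                            type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     col.names = FALSE, eol = "\n")
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (inherits(dataset, "tme_dataset")) {
    write_tsv_strict(dataset$truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Read a 10x-style triplet count directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene ids in the first column) and
#' `barcodes.tsv` under `dir`.
#'
#' @param dir Directory containing the three files.
#' @return A genes-by-cells `dgCMatrix` with gene and cell identifiers as
#'   dimnames.
#' @export
read_tenx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  .assert(length(missing) == 0,
          sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  m <- methods::as(Matrix::readMM(paths[[1]]), "CsparseMatrix")
  genes <- read.delim(paths[[2]], header = FALSE, stringsAsFactors = FALSE)[[1]]
  cells <- readLines(paths[[3]])
  .assert(nrow(m) == length(genes),
          sprintf("features.tsv lists %d genes but matrix.mtx has %d rows",
                  length(genes), nrow(m)))
  .assert(ncol(m) == length(cells),
          sprintf("barcodes.tsv lists %d cells but matrix.mtx has %d columns",
                  length(cells), ncol(m)))
  .assert(!anyDuplicated(genes), "duplicate gene ids in features.tsv")
  .assert(!anyDuplicated(cells), "duplicate cell ids in barcodes.tsv")
  dimnames(m) <- list(genes, cells)
  m
}

#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @param sets Named list of character gene vectors.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) > 0, "GMT file is empty")
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    .assert(length(parts) >= 3, sprintf("malformed GMT line: %s", substr(l, 1, 40)))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  .assert(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

# Deterministic TSV writer used for every table the pipeline emits.
write_tsv_strict <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}
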