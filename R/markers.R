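# Packaged marker references and gene-set registries.
#
# The three-level annotation hierarchy: 13 major lung-TME cell types; 5
# mononuclear-phagocyte (MP) subtypes; and the six-gene macrophage
# classification anchored on AZU1 / CXCL10 / FABP4 / SELENOP / SPP1 / STMN1.
# Major- and MP-level lists use canonical lung-TME markers; each macrophage
# state is anchored by its defining gene plus a small program extension.

.MARKERS_MAJOR <- list(
  CancerCells   = c("EPCAM", "KRT19", "KRT18", "KRT8", "KRT17", "CEACAM5",
                    "S100A14", "MUC1"),
  AT2           = c("SFTPC", "SFTPB", "SFTPA1", "SFTPA2", "NAPSA", "PGC",
                    "SLC34A2", "CTSH"),
  ClubCells     = c("SCGB1A1", "SCGB3A2", "SCGB3A1", "BPIFB1", "CYP2F1",
                    "TFF3", "MUC5B", "LTF"),
  CiliatedCells = c("FOXJ1", "TPPP3", "PIFO", "CAPS", "TMEM190", "C9orf24",
                    "DNAI1", "SNTN"),
  ECs           = c("PECAM1", "CLDN5", "VWF", "CDH5", "RAMP2", "FLT1",
                    "EGFL7", "ACKR1"),
  Fibroblasts   = c("COL1A1", "COL1A2", "COL3A1", "DCN", "LUM", "PDGFRA",
                    "FBLN1", "MGP"),
  PlasmaCells   = c("MZB1", "IGHG1", "JCHAIN", "IGKC", "DERL3", "TNFRSF17",
                    "PRDM1", "XBP1"),
  BCells        = c("MS4A1", "CD79A", "CD79B", "CD19", "BANK1", "VPREB3",
                    "CD24", "FCRL1"),
  TCells        = c("CD3D", "CD3E", "CD3G", "TRAC", "CD2", "IL7R", "LCK",
                    "TRBC2"),
  Neutrophils   = c("FCGR3B", "CSF3R", "CXCR2", "S100A12", "FPR1",
                    "SLC25A37", "BASP1", "G0S2"),
  MastCells     = c("TPSAB1", "TPSB2", "CPA3", "MS4A2", "KIT", "HPGDS",
                    "GATA2", "SLC18A2"),
  MPs           = c("LYZ", "AIF1", "TYROBP", "FCER1G", "CST3", "MS4A7",
                    "ITGAM", "CSF1R"),
  pDCs          = c("LILRA4", "CLEC4C", "IRF7", "TCF4", "IRF8", "PLD4",
                    "SERPINF1", "PTCRA")
)

.MARKERS_MP <- list(
  Macrophages = c("CD68", "MARCO", "C1QA", "C1QB", "APOE", "GPNMB"),
  Monocytes   = c("FCN1", "S100A8", "S100A9", "VCAN", "EREG", "THBS1"),
  MatureDCs   = c("LAMP3", "FSCN1", "CCL19", "CCR7", "BIRC3", "MARCKSL1"),
  cDC1        = c("CLEC9A", "XCR1", "BATF3", "WDFY4", "IDO1", "CPNE3"),
  cDC2        = c("CD1C", "FCER1A", "CLEC10A", "CD1E", "PKIB", "CIITA")
)

.MARKERS_MACRO <- list(
  Macrophages_AZU1    = c("AZU1", "ELANE", "PRTN3", "MPO", "DEFA4", "CTSG"),
  Macrophages_CXCL10  = c("CXCL10", "CXCL9", "CXCL11", "GBP1", "GBP5",
                          "ISG15"),
  Macrophages_FABP4   = c("FABP4", "MRC1", "MSR1", "MCEMP1", "PPARG", "LPL"),
  Macrophages_SELENOP = c("SELENOP", "SLC40A1", "STAB1", "F13A1", "FOLR2",
                          "LYVE1"),
  Macrophages_SPP1    = c("SPP1", "MMP9", "CHI3L1", "VEGFA", "MMP12",
                          "CTSK"),
  Macrophages_STMN1   = c("STMN1", "MKI67", "TOP2A", "TUBA1B", "UBE2C",
                          "BIRC5")
)

#' Packaged hierarchical marker reference
#'
#' Marker gene lists for one annotation level: `"major"` (13 cell types),
#' `"mp"` (5 mononuclear-phagocyte subtypes) or `"macro"` (the six-gene
#' macrophage classification).
#'
#' @param level One of `"major"`, `"mp"`, `"macro"`.
#' @return An object of class `marker_reference`: a list with elements `level`
#'   and `entries` (named list of marker character vectors).
#' @export
default_marker_reference <- function(level = c("major", "mp", "macro")) {
  level <- match.arg(level)
  entries <- switch(level,
                    major = .MARKERS_MAJOR,
                    mp    = .MARKERS_MP,
                    macro = .MARKERS_MACRO)
  marker_reference(level, entries)
}

#' Construct and validate a marker reference
#'
#' @param level Annotation level label.
#' @param entries Named list mapping type name to a non-empty marker vector.
#' @return A `marker_reference` object.
#' @export
marker_reference <- function(level, entries) {
  .assert(level %in% c("major", "mp", "macro"),
          "level must be one of major, mp, macro")
  .assert(is.list(entries) && !is.null(names(entries)) &&
            all(nzchar(names(entries))),
          "entries must be a named list of marker vectors")
  n_expected <- c(major = 13L, mp = 5L, macro = 6L)[[level]]
  .assert(length(entries) == n_expected,
          sprintf("%s reference must contain exactly %d entries, got %d",
                  level, n_expected, length(entries)))
  .assert(all(lengths(entries) > 0), "every type needs at least one marker")
  if (level == "macro") {
    anchors <- c("AZU1", "CXCL10", "FABP4", "SELENOP", "SPP1", "STMN1")
    has_anchor <- vapply(anchors, function(a)
      any(vapply(entries, function(g) a %in% g, logical(1))), logical(1))
    .assert(all(has_anchor),
            sprintf("macro reference must contain the anchor genes: %s",
                    paste(anchors[!has_anchor], collapse = ", ")))
  }
  structure(list(level = level, entries = entries), class = "marker_reference")
}

#' @export
print.marker_reference <- function(x, ...) {
  cat(sprintf("marker_reference (level %s, %d types)\n", x$level,
              length(x$entries)))
  for (nm in names(x$entries))
    cat(sprintf("  %-20s %s\n", nm, paste(x$entries[[nm]], collapse = ", ")))
  invisible(x)
}

# Ligand/receptor genes planted on cancer cells and MPs in the synthetic
# cohort so the interaction stage has signal to find; all are genes of the
# packaged pair database.
.SIM_EXTRA_MARKERS <- list(
  CancerCells = c("EFNA1", "SAA1", "CXCL14", "APP", "HLA-F", "PTGES"),
  MPs         = c("EPHA2", "FPR2", "CXCR4", "TREM2", "VSIR", "PTGER4")
)

# Expressed-but-unplanted background genes guaranteed to be in every simulated
# universe (completes the M1/M2 programs and the decoy receptor genes).
.SIM_BACKGROUND_GENES <- c(
  "IL1B", "TNF", "CD80", "CD86", "NOS2", "IL12B",
  "CD163", "CCL22", "CCL17", "IL10", "TGFB1",
  "IL1R1", "IL1RAP", "CXCR3", "TNFRSF1A"
)

.extdata <- function(...) {
  path <- system.file("extdata", ..., package = "tmeatlas", mustWork = FALSE)
  .assert(nzchar(path) && file.exists(path),
          sprintf("packaged data file not found: %s", paste(..., sep = "/")))
  path
}

#' Packaged M1/M2 macrophage polarization gene sets
#'
#' Canonical pro-inflammatory (M1) and alternatively activated (M2) programs,
#' stored as GMT under `inst/extdata`. Override by supplying your own GMT to
#' the scoring functions.
#'
#' @return Named list with character vectors `M1` and `M2`.
#' @export
default_polarization_sets <- function() {
  read_gmt(.extdata("polarization_sets.gmt"))
}

#' Packaged toy pathway collection for over-representation analysis
#'
#' A small synthetic collection (~30 sets) over the simulated gene universe,
#' standing in for live GO/KEGG databases which this package never queries.
#'
#' @return Named list of character gene vectors.
#' @export
toy_pathway_collection <- function() {
  read_gmt(.extdata("toy_pathways_synthetic.gmt"))
}

#' Packaged ligand-receptor pair database
#'
#' A mini database of expression-level ligand-receptor pairs, including
#' EFNA1-EPHA2, SAA1-FPR2, APP-FPR2, CXCL14-CXCR4, APP-TREM2 and HLA-F-VSIR.
#' Prostaglandin signalling (PGE2 to PTGER receptors) is a metabolite-receptor
#' axis with no ligand transcript; it is represented by the synthase proxy
#' pair PTGES-PTGER4, which scores the pathway's transcriptional footprint,
#' not the metabolite itself.
#'
#' @param path Optional path to a custom TSV with columns `pair`,
#'   `ligand_genes`, `receptor_genes` (complex members comma-separated).
#' @return Data frame with columns `pair`, `ligand_genes` (list column),
#'   `receptor_genes` (list column).
#' @export
default_lr_pairs <- function(path = NULL) {
  path <- path %||% .extdata("lr_pairs_synthetic.tsv")
  df <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("pair", "ligand_genes", "receptor_genes") %in% names(df)),
          "LR table needs columns pair, ligand_genes, receptor_genes")
  split_genes <- function(x) strsplit(x, ",", fixed = TRUE)
  out <- data.frame(pair = df$pair, stringsAsFactors = FALSE)
  out$ligand_genes <- lapply(split_genes(df$ligand_genes), trimws)
  out$receptor_genes <- lapply(split_genes(df$receptor_genes), trimws)
  .assert(all(lengths(out$ligand_genes) > 0) &&
            all(lengths(out$receptor_genes) > 0),
          "every pair needs at least one ligand and one receptor gene")
  out
}

#' Packaged synthetic IHC specimen fixture
#'
#' A seven-specimen synthetic cohort whose composite scores split 3 / 4 into
#' the RUNX3_Neg and RUNX3_Pos groups.
#'
#' @return Data frame with `specimen_id`, `percent_positive`, `intensity`.
#' @export
example_ihc_specimens <- function() {
  read_ihc(.extdata("ihc_specimens_synthetic.tsv"))
}
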