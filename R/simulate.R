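# Synthetic scRNA-seq cohort generator with planted hierarchical cell types.
#
# Counts follow a negative binomial: gene baseline means are log-normal, each
# population multiplies its marker genes by a fold-change, and every cell
# carries a log-normal library-size factor. Composition differs by tissue
# group; the packaged tables encode the qualitative enrichment directions the
# pipeline is meant to recover (fibroblasts the sole type preferred in
# RUNX3_Pos; macrophages depleted and monocytes enriched in RUNX3_Neg; the
# six-gene macrophage states shifting between groups).

# Planted within-group composition (percent). Columns: NOR, RUNX3_Neg,
# RUNX3_Pos; each sums to 100. Magnitudes are free design parameters chosen
# for clear separation of the observed/expected ratio from 1.
.COMPOSITION_MAJOR <- matrix(
  c( 9.0, 12.0,  8.4,   # CancerCells
    14.0,  3.5,  7.0,   # AT2
     4.0,  8.0,  4.8,   # ClubCells
     4.0,  8.0,  4.8,   # CiliatedCells
     8.5,  4.5,  5.2,   # ECs
     2.0, 20.0, 28.5,   # Fibroblasts
     3.0,  6.0,  3.6,   # PlasmaCells
     4.0,  7.0,  4.4,   # BCells
    21.0,  8.0, 11.7,   # TCells
     3.0,  6.0,  3.6,   # Neutrophils
     3.0,  5.0,  3.2,   # MastCells
    22.5,  8.0, 12.4,   # MPs
     2.0,  4.0,  2.4),  # pDCs
  ncol = 3, byrow = TRUE,
  dimnames = list(names(.MARKERS_MAJOR), TISSUE_GROUPS))

.COMPOSITION_MP <- matrix(
  c(60, 32, 58,   # Macrophages
    15, 30, 10,   # Monocytes
     4, 15, 12,   # MatureDCs
    14,  6,  5,   # cDC1
     7, 17, 15),  # cDC2
  ncol = 3, byrow = TRUE,
  dimnames = list(names(.MARKERS_MP), TISSUE_GROUPS))

.COMPOSITION_MACRO <- matrix(
  c( 8,  4, 15,   # Macrophages_AZU1
     8, 18, 15,   # Macrophages_CXCL10
    49, 15,  8,   # Macrophages_FABP4
    12, 22, 21,   # Macrophages_SELENOP
    13, 25, 24,   # Macrophages_SPP1
    10, 16, 17),  # Macrophages_STMN1
  ncol = 3, byrow = TRUE,
  dimnames = list(names(.MARKERS_MACRO), TISSUE_GROUPS))

.default_samples <- function() {
  data.frame(
    sample_id = c("NOR_1", "NOR_2", "NOR_3", "NEG_1", "NEG_2", "NEG_3",
                  "POS_1", "POS_2", "POS_3", "POS_4"),
    group = c(rep("NOR", 3), rep("RUNX3_Neg", 3), rep("RUNX3_Pos", 4)),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Low-level constructor; most users want [default_config()]. Populations are
#' given as a named list of marker vectors; every marker may appear in exactly
#' one population.
#'
#' @param populations Named list: population name -> marker gene vector.
#' @param group_proportions Named list: tissue group -> named proportion
#'   vector over populations, each summing to 1.
#' @param samples Data frame with columns `sample_id`, `group`.
#' @param level Annotation level the populations live on (`"major"`, `"mp"`,
#'   `"macro"`).
#' @param n_genes Total genes in the universe (markers plus background and
#'   numbered filler genes).
#' @param n_cells_per_sample Cells simulated per sample.
#' @param marker_fold Fold-change applied to a population's markers
#'   (recycled; must be >= 1).
#' @param nb_dispersion Negative-binomial over-dispersion `phi`
#'   (variance = mu + phi * mu^2).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene baseline mean.
#' @param library_size_sd Standard deviation (log scale) of the per-cell
#'   library factor; 0 disables it.
#' @param exact_proportions If `TRUE`, allocate cell types by largest-remainder
#'   rounding instead of multinomial draws.
#' @param extra_genes Character vector of additional background genes to
#'   include in the universe without any planted fold.
#' @param shared_markers Markers planted (at `marker_fold`) in every cell of
#'   the dataset -- the ancestor-level identity genes of a flat sub-level
#'   scenario (e.g. the MPs major markers when simulating MP subtypes).
#' @param seed Integer seed; all draws flow from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(populations, group_proportions, samples = .default_samples(),
                       level = c("major", "mp", "macro"), n_genes = 1000,
                       n_cells_per_sample = 500, marker_fold = 8,
                       nb_dispersion = 0.5, baseline_log_mean = 0,
                       baseline_log_sd = 1, library_size_sd = 0.2,
                       exact_proportions = FALSE, extra_genes = character(),
                       shared_markers = character(), seed = 1L) {
  level <- match.arg(level)
  cfg <- structure(list(
    populations = populations,
    marker_fold = rep_len(marker_fold, length(populations)),
    group_proportions = group_proportions,
    samples = samples, level = level,
    n_genes = as.integer(n_genes),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    nb_dispersion = nb_dispersion,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    library_size_sd = library_size_sd,
    exact_proportions = isTRUE(exact_proportions),
    extra_genes = extra_genes,
    shared_markers = shared_markers,
    seed = as.integer(seed)), class = "sim_config")
  names(cfg$marker_fold) <- names(populations)
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks proportion normalization (within 1e-9 per group), marker uniqueness
#' across populations, fold-changes >= 1, and sizes.
#'
#' @param config A `sim_config`.
#' @return `config`, invisibly; errors describe the first violation.
#' @export
validate_sim_config <- function(config) {
  .assert(inherits(config, "sim_config"), "not a sim_config object")
  pops <- config$populations
  .assert(is.list(pops) && length(pops) > 0 && !is.null(names(pops)),
          "populations must be a non-empty named list")
  all_markers <- unlist(pops, use.names = FALSE)
  dup <- unique(all_markers[duplicated(all_markers)])
  .assert(length(dup) == 0,
          sprintf("marker gene(s) in more than one population: %s",
                  paste(dup, collapse = ", ")))
  clash <- intersect(config$shared_markers, all_markers)
  .assert(length(clash) == 0,
          sprintf("shared marker(s) also listed in a population: %s",
                  paste(clash, collapse = ", ")))
  .assert(all(config$marker_fold >= 1), "marker fold-changes must be >= 1")
  .assert(is.data.frame(config$samples) &&
            all(c("sample_id", "group") %in% names(config$samples)),
          "samples needs columns sample_id, group")
  groups <- unique(config$samples$group)
  for (g in groups) {
    p <- config$group_proportions[[g]]
    .assert(!is.null(p), sprintf("no proportions given for group %s", g))
    .assert(setequal(names(p), names(pops)),
            sprintf("group %s proportions must cover all populations", g))
    .assert(abs(sum(p) - 1) < 1e-9,
            sprintf("group %s proportions sum to %.12f, not 1", g, sum(p)))
    .assert(all(p >= 0 & p <= 1),
            sprintf("group %s proportions must lie in [0, 1]", g))
  }
  n_named <- length(all_markers) + length(config$extra_genes) +
    length(config$shared_markers)
  .assert(config$n_genes >= n_named,
          sprintf("n_genes (%d) must cover the %d marker/background genes",
                  config$n_genes, n_named))
  .assert(config$n_cells_per_sample > 0, "n_cells_per_sample must be positive")
  .assert(config$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(config$library_size_sd >= 0, "library_size_sd must be non-negative")
  invisible(config)
}

#' Default configuration for the bundled scenarios
#'
#' Three flat scenarios mirror the annotation hierarchy: `major13` plants the
#' 13 major cell types, `mp5` the five mononuclear-phagocyte subtypes, and
#' `macro6` the six macrophage states. Group composition encodes the
#' qualitative enrichment directions the pipeline should recover; cells are
#' spread over 10 samples (3 normal, 3 RUNX3_Neg, 4 RUNX3_Pos).
#'
#' @param scenario One of `"major13"`, `"mp5"`, `"macro6"`.
#' @param ... Overrides passed to [sim_config()] (e.g. `n_cells_per_sample`,
#'   `marker_fold`, `seed`, `exact_proportions`).
#' @return A `sim_config`.
#' @examples
#' cfg <- default_config("macro6", n_cells_per_sample = 100, seed = 7)
#' names(cfg$populations)
#' @export
default_config <- function(scenario = c("major13", "mp5", "macro6"), ...) {
  .assert(is.character(scenario) && length(scenario) == 1 &&
            scenario %in% c("major13", "mp5", "macro6"),
          sprintf("unknown scenario '%s' (expected major13, mp5 or macro6)",
                  paste(scenario, collapse = ",")),
          class = "tmeatlas_scenario_error")
  spec <- switch(scenario,
    major13 = list(markers = .MARKERS_MAJOR, comp = .COMPOSITION_MAJOR,
                   level = "major"),
    mp5     = list(markers = .MARKERS_MP, comp = .COMPOSITION_MP,
                   level = "mp"),
    macro6  = list(markers = .MARKERS_MACRO, comp = .COMPOSITION_MACRO,
                   level = "macro"))
  props <- lapply(TISSUE_GROUPS, function(g) {
    p <- spec$comp[, g] / sum(spec$comp[, g])
    setNames(p, rownames(spec$comp))
  })
  names(props) <- TISSUE_GROUPS
  # the full marker registry is always part of the universe so every
  # annotation level can be scored; off-scenario markers carry no fold
  extra <- unique(c(unlist(.SIM_EXTRA_MARKERS, use.names = FALSE),
                    .SIM_BACKGROUND_GENES,
                    unlist(.MARKERS_MAJOR, use.names = FALSE),
                    unlist(.MARKERS_MP, use.names = FALSE),
                    unlist(.MARKERS_MACRO, use.names = FALSE)))
  # flat sub-level scenarios still express their ancestor identity genes
  shared <- switch(spec$level,
                   major = character(),
                   mp = c(.MARKERS_MAJOR$MPs, .SIM_EXTRA_MARKERS$MPs),
                   macro = c(.MARKERS_MAJOR$MPs, .SIM_EXTRA_MARKERS$MPs,
                             .MARKERS_MP$Macrophages))
  extra <- setdiff(extra, c(unlist(spec$markers, use.names = FALSE), shared))
  sim_config(populations = spec$markers, group_proportions = props,
             level = spec$level, extra_genes = extra,
             shared_markers = shared, ...)
}

# Largest-remainder allocation of n cells to proportions p.
.exact_allocation <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra_idx <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra_idx] <- base[extra_idx] + 1
  }
  as.integer(base)
}

.draw_labels <- function(n, p, exact) {
  if (exact) {
    rep(names(p), .exact_allocation(n, p))
  } else {
    sample(names(p), n, replace = TRUE, prob = p)
  }
}

# NB count generation: mu_base per gene, per-cell library factors, and a named
# list cell -> marker fold assignment expressed as population labels plus a
# lookup of fold vectors per population.
.generate_counts <- function(mu_base, lib, fold_rows, dispersion) {
  n_genes <- length(mu_base)
  n_cells <- length(lib)
  mu <- outer(mu_base, lib)
  for (k in seq_along(fold_rows)) {
    fr <- fold_rows[[k]]
    if (length(fr$rows) && length(fr$cells))
      mu[fr$rows, fr$cells] <- mu[fr$rows, fr$cells] * fr$fold
  }
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
                   nrow = n_genes)
  counts
}

#' Simulate a synthetic dataset from a configuration
#'
#' Draws each cell's type from its sample's group proportions (multinomial, or
#' exact largest-remainder allocation when `exact_proportions`), gene baseline
#' means from a log-normal, multiplies each population's marker genes by its
#' fold-change, and samples negative-binomial counts with a per-cell
#' log-normal library factor. Fully reproducible from `config$seed`.
#'
#' @param config A validated `sim_config`.
#' @return An object of class `tme_dataset`: list with `counts` (genes x cells
#'   `dgCMatrix`), `truth` (per-cell data frame with columns `cell_id`,
#'   `sample_id`, `group`, `major_type`, `mp_subtype`, `macro_subtype`) and
#'   `config`.
#' @examples
#' d <- simulate_dataset(default_config("mp5", n_cells_per_sample = 50,
#'                                      n_genes = 200, seed = 1))
#' dim(d$counts)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    gene_ids <- .gene_universe(config)
    n_cells_total <- nrow(config$samples) * config$n_cells_per_sample
    labels <- character(n_cells_total)
    sample_id <- character(n_cells_total)
    group <- character(n_cells_total)
    at <- 1L
    for (i in seq_len(nrow(config$samples))) {
      n <- config$n_cells_per_sample
      g <- config$samples$group[[i]]
      idx <- at:(at + n - 1L)
      labels[idx] <- .draw_labels(n, config$group_proportions[[g]],
                                  config$exact_proportions)
      sample_id[idx] <- config$samples$sample_id[[i]]
      group[idx] <- g
      at <- at + n
    }
    cell_ids <- sprintf("%s_C%04d", sample_id,
                        ave(seq_len(n_cells_total), sample_id, FUN = seq_along))
    counts <- .simulate_counts_for_labels(config, gene_ids,
                                          list(setNames(labels, cell_ids)))
    truth <- .truth_frame(config$level, cell_ids, sample_id, group, labels)
    structure(list(counts = counts, truth = truth, config = config),
              class = "tme_dataset")
  })
}

.gene_universe <- function(config) {
  named <- c(unlist(config$populations, use.names = FALSE),
             config$shared_markers, config$extra_genes)
  n_filler <- config$n_genes - length(named)
  c(named, sprintf("GENE%05d", seq_len(n_filler)))
}

# Shared count generation: label_sets is a list of named label vectors
# (cell_id -> population), one per hierarchy level; fold lookups come from the
# corresponding population lists in `pop_sets` (parallel list). For the flat
# case both lists have length 1.
.simulate_counts_for_labels <- function(config, gene_ids, label_sets,
                                        pop_sets = NULL, fold_sets = NULL) {
  pop_sets <- pop_sets %||% list(config$populations)
  fold_sets <- fold_sets %||% list(config$marker_fold)
  cell_ids <- names(label_sets[[1]])
  n_cells <- length(cell_ids)
  mu_base <- rlnorm(length(gene_ids), config$baseline_log_mean,
                    config$baseline_log_sd)
  lib <- if (config$library_size_sd > 0)
    rlnorm(n_cells, 0, config$library_size_sd) else rep(1, n_cells)
  fold_rows <- list()
  if (length(config$shared_markers)) {
    rows <- match(config$shared_markers, gene_ids)
    fold_rows[[1L]] <- list(rows = rows[!is.na(rows)],
                            cells = seq_len(n_cells),
                            fold = max(fold_sets[[1]]))
  }
  for (lvl in seq_along(label_sets)) {
    labs <- label_sets[[lvl]]
    pops <- pop_sets[[lvl]]
    folds <- fold_sets[[lvl]]
    for (pop in names(pops)) {
      cells <- which(!is.na(labs) & labs == pop)
      rows <- match(pops[[pop]], gene_ids)
      rows <- rows[!is.na(rows)]
      if (length(cells) && length(rows))
        fold_rows[[length(fold_rows) + 1L]] <-
          list(rows = rows, cells = cells, fold = folds[[pop]])
    }
  }
  counts <- .generate_counts(mu_base, lib, fold_rows, config$nb_dispersion)
  dimnames(counts) <- list(gene_ids, cell_ids)
  methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
}

.truth_frame <- function(level, cell_ids, sample_id, group, labels) {
  truth <- data.frame(cell_id = cell_ids, sample_id = sample_id, group = group,
                      major_type = NA_character_, mp_subtype = NA_character_,
                      macro_subtype = NA_character_, stringsAsFactors = FALSE)
  if (level == "major") {
    truth$major_type <- labels
  } else if (level == "mp") {
    truth$major_type <- "MPs"
    truth$mp_subtype <- labels
  } else {
    truth$major_type <- "MPs"
    truth$mp_subtype <- "Macrophages"
    truth$macro_subtype <- labels
  }
  truth
}

#' Simulate a hierarchical cohort
#'
#' Combines the three scenarios into one dataset: every cell gets a major
#' type; cells of major type `MPs` additionally draw an MP subtype; MP-subtype
#' `Macrophages` additionally draw a six-gene macrophage state. Marker
#' fold-changes are additive down the path (an SPP1-state macrophage carries
#' MP major markers, macrophage subtype markers and SPP1-state markers).
#'
#' @param n_cells_per_sample Cells per sample (10 samples).
#' @param n_genes Gene universe size.
#' @param marker_fold Fold-change for planted markers at every level.
#' @param seed Integer seed.
#' @param ... Further overrides forwarded to [sim_config()] (applied to the
#'   major-level configuration that carries the generator parameters).
#' @return A `tme_dataset` whose `truth` has all three label columns filled
#'   according to the hierarchy (subtype columns are `NA` off-path).
#' @export
simulate_cohort <- function(n_cells_per_sample = 500, n_genes = 1200,
                            marker_fold = 8, seed = 1L, ...) {
  cfg_major <- default_config("major13", n_cells_per_sample = n_cells_per_sample,
                              n_genes = n_genes, marker_fold = marker_fold,
                              seed = seed, ...)
  cfg_mp <- default_config("mp5", seed = seed)
  cfg_macro <- default_config("macro6", seed = seed)
  extra <- unique(c(cfg_major$extra_genes,
                    unlist(cfg_mp$populations, use.names = FALSE),
                    unlist(cfg_macro$populations, use.names = FALSE)))
  cfg_major$extra_genes <- setdiff(extra,
                                   unlist(cfg_major$populations, use.names = FALSE))
  validate_sim_config(cfg_major)
  withr::with_seed(seed, {
    gene_ids <- .gene_universe(cfg_major)
    samples <- cfg_major$samples
    n_total <- nrow(samples) * cfg_major$n_cells_per_sample
    sample_id <- rep(samples$sample_id, each = cfg_major$n_cells_per_sample)
    group <- rep(samples$group, each = cfg_major$n_cells_per_sample)
    major <- character(n_total)
    for (s in unique(sample_id)) {
      idx <- which(sample_id == s)
      major[idx] <- .draw_labels(length(idx),
                                 cfg_major$group_proportions[[group[idx][1]]],
                                 cfg_major$exact_proportions)
    }
    mp <- rep(NA_character_, n_total)
    idx_mp <- which(major == "MPs")
    for (g in TISSUE_GROUPS) {
      idx <- idx_mp[group[idx_mp] == g]
      if (length(idx))
        mp[idx] <- .draw_labels(length(idx), cfg_mp$group_proportions[[g]],
                                cfg_major$exact_proportions)
    }
    macro <- rep(NA_character_, n_total)
    idx_mac <- which(!is.na(mp) & mp == "Macrophages")
    for (g in TISSUE_GROUPS) {
      idx <- idx_mac[group[idx_mac] == g]
      if (length(idx))
        macro[idx] <- .draw_labels(length(idx), cfg_macro$group_proportions[[g]],
                                   cfg_major$exact_proportions)
    }
    cell_ids <- sprintf("%s_C%04d", sample_id,
                        ave(seq_len(n_total), sample_id, FUN = seq_along))
    # ligand/receptor extras ride along with their host populations
    pops_major <- cfg_major$populations
    pops_major$CancerCells <- c(pops_major$CancerCells,
                                .SIM_EXTRA_MARKERS$CancerCells)
    pops_major$MPs <- c(pops_major$MPs, .SIM_EXTRA_MARKERS$MPs)
    counts <- .simulate_counts_for_labels(
      cfg_major, gene_ids,
      label_sets = list(setNames(major, cell_ids), setNames(mp, cell_ids),
                        setNames(macro, cell_ids)),
      pop_sets = list(pops_major, cfg_mp$populations, cfg_macro$populations),
      fold_sets = list(cfg_major$marker_fold, cfg_mp$marker_fold,
                       cfg_macro$marker_fold))
    truth <- data.frame(cell_id = cell_ids, sample_id = sample_id,
                        group = group, major_type = major, mp_subtype = mp,
                        macro_subtype = macro, stringsAsFactors = FALSE)
    structure(list(counts = counts, truth = truth, config = cfg_major),
              class = "tme_dataset")
  })
}

#' Expected Ro/e of a configuration at infinite sample size
#'
#' Plugs the planted group proportions and group cell totals into the
#' observed-over-expected formula, giving the ratio the composition table
#' would converge to. Used as a truth oracle for parameter recovery.
#'
#' @param config A `sim_config`.
#' @return Numeric matrix, populations x tissue groups.
#' @examples
#' planted_roe(default_config("mp5"))
#' @export
planted_roe <- function(config) {
  validate_sim_config(config)
  groups <- unique(config$samples$group)
  n_per_group <- vapply(groups, function(g)
    sum(config$samples$group == g) * config$n_cells_per_sample, numeric(1))
  O <- vapply(groups, function(g)
    config$group_proportions[[g]][names(config$populations)] *
      n_per_group[[g]], numeric(length(config$populations)))
  dimnames(O) <- list(names(config$populations), groups)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  O / E
}

#' @export
print.tme_dataset <- function(x, ...) {
  cat(sprintf("tme_dataset: %d genes x %d cells, %d samples, level %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$truth$sample_id)), x$config$level))
  invisible(x)
}
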