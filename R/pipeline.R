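# End-to-end orchestration: simulate (or read) -> IHC scoring -> hierarchical
# annotation -> Ro/e per level -> M1/M2 polarization report -> differential
# expression + over-representation -> ligand-receptor interactions, with a
# JSON manifest hashing every produced file.

#' Build a pipeline run configuration
#'
#' Exactly one of a simulation scenario or a set of real input paths must be
#' given.
#'
#' @param out_dir Output directory.
#' @param scenario `"cohort"` (hierarchical, the default study design) or one
#'   of the flat scenarios `"major13"`, `"mp5"`, `"macro6"`; `NULL` when real
#'   inputs are supplied.
#' @param counts_dir Directory with `matrix.mtx`/`features.tsv`/`barcodes.tsv`
#'   (real-input mode).
#' @param metadata_path Per-cell metadata TSV (`cell_id`, `sample_id`,
#'   `group`) for real-input mode.
#' @param ihc_path Specimen TSV; defaults to the packaged synthetic cohort.
#' @param seed Root seed for every stochastic stage.
#' @param n_cells_per_sample,n_genes,marker_fold Generator scale (simulation
#'   mode).
#' @param resolution Clustering resolution.
#' @param lfc_cut,q_cut Volcano cutoffs.
#' @param n_perm Ligand-receptor permutations.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, scenario = "cohort", counts_dir = NULL,
                       metadata_path = NULL, ihc_path = NULL, seed = 1L,
                       n_cells_per_sample = 500, n_genes = 1200,
                       marker_fold = 8, resolution = 1.5, lfc_cut = 1,
                       q_cut = 0.05, n_perm = 99) {
  has_sim <- !is.null(scenario)
  has_real <- !is.null(counts_dir) || !is.null(metadata_path)
  .assert(xor(has_sim, has_real),
          "exactly one of {simulation scenario, real input paths} must be set")
  if (has_real)
    .assert(!is.null(counts_dir) && !is.null(metadata_path),
            "real-input mode needs both counts_dir and metadata_path")
  if (has_sim)
    .assert(scenario %in% c("cohort", "major13", "mp5", "macro6"),
            sprintf("unknown scenario '%s'", scenario))
  structure(list(out_dir = out_dir, scenario = scenario,
                 counts_dir = counts_dir, metadata_path = metadata_path,
                 ihc_path = ihc_path, seed = as.integer(seed),
                 n_cells_per_sample = n_cells_per_sample, n_genes = n_genes,
                 marker_fold = marker_fold, resolution = resolution,
                 lfc_cut = lfc_cut, q_cut = q_cut, n_perm = n_perm),
            class = "run_config")
}

#' Validate a 10x-style input directory and metadata table
#'
#' Checks the MatrixMarket header, agreement of matrix dimensions with the
#' feature and barcode files, metadata coverage of every barcode, and the
#' tissue-group vocabulary.
#'
#' @param counts_dir Directory with the three matrix files.
#' @param metadata_path Optional metadata TSV to check against the barcodes.
#' @return Data frame report (`file`, `line`, `problem`); zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(counts_dir, metadata_path = NULL) {
  report <- list()
  note <- function(file, line, problem)
    report[[length(report) + 1L]] <<- data.frame(
      file = file, line = line, problem = problem, stringsAsFactors = FALSE)
  mtx <- file.path(counts_dir, "matrix.mtx")
  fts <- file.path(counts_dir, "features.tsv")
  bcs <- file.path(counts_dir, "barcodes.tsv")
  for (f in c(mtx, fts, bcs))
    if (!file.exists(f)) note(f, NA_integer_, "file missing")
  if (length(report) == 0) {
    head2 <- readLines(mtx, n = 2)
    if (!grepl("^%%MatrixMarket matrix coordinate", head2[1]))
      note(mtx, 1L, "not a MatrixMarket coordinate header")
    dims <- suppressWarnings(as.integer(strsplit(trimws(head2[2]), "\\s+")[[1]]))
    n_genes <- length(readLines(fts))
    n_cells <- length(readLines(bcs))
    if (length(dims) >= 2 && !anyNA(dims[1:2])) {
      if (dims[1] != n_genes)
        note(fts, n_genes,
             sprintf("features.tsv has %d rows but matrix declares %d genes",
                     n_genes, dims[1]))
      if (dims[2] != n_cells)
        note(bcs, n_cells,
             sprintf("barcodes.tsv has %d rows but matrix declares %d cells",
                     n_cells, dims[2]))
    } else {
      note(mtx, 2L, "unreadable dimensions line")
    }
    if (!is.null(metadata_path)) {
      if (!file.exists(metadata_path)) {
        note(metadata_path, NA_integer_, "file missing")
      } else {
        meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
        need <- c("cell_id", "sample_id", "group")
        lack <- setdiff(need, names(meta))
        if (length(lack))
          note(metadata_path, 1L,
               sprintf("missing column(s): %s", paste(lack, collapse = ", ")))
        if (!length(lack)) {
          barcodes <- readLines(bcs)
          uncovered <- setdiff(barcodes, meta$cell_id)
          if (length(uncovered))
            note(metadata_path, NA_integer_,
                 sprintf("%d barcode(s) lack metadata (e.g. %s)",
                         length(uncovered), uncovered[1]))
          bad_groups <- setdiff(unique(meta$group), TISSUE_GROUPS)
          for (bg in bad_groups)
            note(metadata_path, which(meta$group == bg)[1] + 1L,
                 sprintf("unknown group label '%s' (allowed: %s)", bg,
                         paste(TISSUE_GROUPS, collapse = ", ")))
        }
      }
    }
  }
  if (length(report) == 0)
    return(data.frame(file = character(), line = integer(),
                      problem = character(), stringsAsFactors = FALSE))
  do.call(rbind, report)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) .stop_tme(
    sprintf("stage %s failed: %s", name, conditionMessage(e)),
    class = "tmeatlas_stage_error"))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order, writing every result table under
#' `config$out_dir` and a `manifest.json` with an md5 content hash for each
#' produced file. A failing stage aborts with an error naming the stage.
#' Identical configuration and seed yield byte-identical output tables.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list with `stages`, `files`, `params`,
#'   `versions`, `wall_time_s`).
#' @export
run_all <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from run_config()")
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  produced <- character()
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_tsv_strict(df, path)
    produced <<- c(produced, path)
    path
  }

  if (!is.null(config$scenario)) {
    dataset <- .stage("simulate", {
      if (config$scenario == "cohort")
        simulate_cohort(n_cells_per_sample = config$n_cells_per_sample,
                        n_genes = config$n_genes,
                        marker_fold = config$marker_fold, seed = config$seed)
      else
        simulate_dataset(default_config(
          config$scenario, n_cells_per_sample = config$n_cells_per_sample,
          n_genes = config$n_genes, marker_fold = config$marker_fold,
          seed = config$seed))
    })
    counts_dir <- file.path(out, "counts")
    .stage("simulate", write_dataset(dataset, counts_dir))
    produced <- c(produced, file.path(counts_dir,
                                      c("matrix.mtx", "features.tsv",
                                        "barcodes.tsv", "truth.tsv")))
    counts <- dataset$counts
    metadata <- dataset$truth[, c("cell_id", "sample_id", "group")]
    stages <- c(stages, "simulate")
  } else {
    rep <- .stage("validate", validate_inputs(config$counts_dir,
                                              config$metadata_path))
    .assert(nrow(rep) == 0, paste("input validation failed:",
                                  paste(rep$problem, collapse = "; ")))
    counts <- .stage("read", read_tenx(config$counts_dir))
    metadata <- .stage("read", read.delim(config$metadata_path,
                                          stringsAsFactors = FALSE))
    stages <- c(stages, "validate", "read")
  }

  scored <- .stage("ihc_score", {
    specimens <- if (is.null(config$ihc_path)) example_ihc_specimens()
                 else read_ihc(config$ihc_path)
    score_and_group(specimens)
  })
  emit(scored, "ihc_scored.tsv")
  stages <- c(stages, "ihc_score")

  # flat sub-level scenarios enter the hierarchy at their own level
  start_level <- switch(config$scenario %||% "cohort",
                        mp5 = "mp", macro6 = "macro", "major")
  ann <- .stage("annotate",
                annotate_hierarchy(counts, metadata,
                                   resolution = config$resolution,
                                   seed = config$seed,
                                   start_level = start_level))
  emit(ann, "annotation.tsv")
  stages <- c(stages, "annotate")

  norm <- normalize_log(counts)
  level_fields <- c(major = "major_type", mp = "mp_subtype",
                    macro = "macro_subtype")
  .stage("roe", {
    for (lvl in names(level_fields)) {
      field <- level_fields[[lvl]]
      if (all(is.na(ann[[field]]))) next
      rt <- roe_from_annotation(ann, type_field = field)
      calls <- preference_calls(rt)
      wide <- data.frame(type = rownames(rt$roe), round(rt$roe, 6),
                         check.names = FALSE, stringsAsFactors = FALSE)
      emit(wide, sprintf("roe_wide_%s.tsv", lvl))
      emit(calls$long, sprintf("roe_long_%s.tsv", lvl))
    }
  })
  stages <- c(stages, "roe")

  if (!all(is.na(ann$macro_subtype))) {
    report <- .stage("score_modules",
                     m1_m2_report(norm, ann, seed = config$seed))
    emit(report, "m1_m2_scores.tsv")
    stages <- c(stages, "score_modules")
  }

  mp_cells <- ann$cell_id[ann$major_type == "MPs"]
  pos_cells <- intersect(mp_cells, ann$cell_id[ann$group == "RUNX3_Pos"])
  neg_cells <- intersect(mp_cells, ann$cell_id[ann$group == "RUNX3_Neg"])
  if (length(pos_cells) >= 2 && length(neg_cells) >= 2) {
    de <- .stage("de", {
      res <- wilcoxon_de(norm, pos_cells, neg_cells)
      volcano_classify(res, lfc_cut = config$lfc_cut, q_cut = config$q_cut)
    })
    emit(de, "de_mps_pos_vs_neg.tsv")
    stages <- c(stages, "de")
    up <- de$gene[de$direction == "up"]
    if (length(up) > 0) {
      enr <- .stage("enrich", {
        universe <- rownames(norm)[Matrix::rowSums(norm) > 0]
        hypergeom_ora(intersect(up, universe), toy_pathway_collection(),
                      universe)
      })
      emit(enr, "enrichment_up.tsv")
      stages <- c(stages, "enrich")
    }
  }

  lr_res <- .stage("lr", {
    pairs <- default_lr_pairs()
    res <- list()
    for (g in c("RUNX3_Pos", "RUNX3_Neg")) {
      senders <- ann$cell_id[ann$major_type == "CancerCells" & ann$group == g]
      receivers <- ann$cell_id[ann$major_type == "MPs" & ann$group == g]
      if (length(senders) < 2 || length(receivers) < 2) next
      r <- suppressWarnings(
        permutation_test(norm, senders, receivers, pairs,
                         n_perm = config$n_perm, seed = config$seed))
      r <- cbind(sender_group = g, receiver_group = g, r)
      res[[g]] <- r
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  if (!is.null(lr_res)) {
    rownames(lr_res) <- NULL
    emit(lr_res, "lr_interactions.tsv")
    stages <- c(stages, "lr")
  }

  manifest <- list(
    stages = stages,
    files = lapply(stats::setNames(produced, basename(produced)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    params = config[setdiff(names(config), "out_dir")],
    versions = list(tmeatlas = as.character(packageVersion("tmeatlas")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    wall_time_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
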