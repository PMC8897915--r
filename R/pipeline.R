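#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()]. Unknown keys are
#' rejected; every value is validated through the constructor of the stage
#' it belongs to.
#'
#' @param min_mapq,include_duplicates,include_secondary,include_qcfail read
#'   filter, see [read_filter()].
#' @param gc_min,gc_max,mappability_min,median_depth_min,median_depth_max,length_min,length_max
#'   QC thresholds, see [qc_thresholds()].
#' @param mode background-selection mode, see [select_neighbors()];
#'   `"global"` runs the chromosome-wide baseline instead.
#' @param k background regions per region.
#' @param seed master seed (background sampling and CBS permutations).
#' @param K,K_max,max_iter,tol,pseudocount latent-model settings, see
#'   [latent_config()].
#' @param alpha,n_perm,min_width segmentation settings, see [cbs_segment()].
#' @param max_gap_bp call merging distance, see [merge_calls()].
#' @param workers parallel workers for the fork-join normalization.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mapq = 20L, include_duplicates = FALSE,
                            include_secondary = FALSE, include_qcfail = FALSE,
                            gc_min = 0.20, gc_max = 0.80,
                            mappability_min = 0.9,
                            median_depth_min = 20, median_depth_max = 4000,
                            length_min = 20, length_max = 2000,
                            mode = "pearson", k = 100L, seed = 1L,
                            K = "auto", K_max = 5L, max_iter = 100L,
                            tol = 1e-6, pseudocount = 0.5,
                            alpha = 0.01, n_perm = 1000L, min_width = 1L,
                            max_gap_bp = 50000, workers = 1L) {
  stopifnot(mode %in% c("pearson", "random", "gc", "length", "mean_depth",
                        "global"),
            workers >= 1L)
  cfg <- list(min_mapq = min_mapq, include_duplicates = include_duplicates,
              include_secondary = include_secondary,
              include_qcfail = include_qcfail,
              gc_min = gc_min, gc_max = gc_max,
              mappability_min = mappability_min,
              median_depth_min = median_depth_min,
              median_depth_max = median_depth_max,
              length_min = length_min, length_max = length_max,
              mode = mode, k = as.integer(k), seed = as.integer(seed),
              K = K, K_max = K_max, max_iter = max_iter, tol = tol,
              pseudocount = pseudocount, alpha = alpha,
              n_perm = as.integer(n_perm), min_width = as.integer(min_width),
              max_gap_bp = max_gap_bp, workers = as.integer(workers))
  # validate through the stage constructors
  read_filter(cfg$min_mapq, cfg$include_duplicates, cfg$include_secondary,
              cfg$include_qcfail)
  qc_thresholds(cfg$gc_min, cfg$gc_max, cfg$mappability_min,
                cfg$median_depth_min, cfg$median_depth_max,
                cfg$length_min, cfg$length_max)
  latent_config(cfg$K, cfg$K_max, cfg$max_iter, cfg$tol, cfg$pseudocount)
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline_config from a flat key = value list
#'
#' @param values named list (e.g. parsed from a config file); unknown keys
#'   are an error.
#' @export
pipeline_config_from_list <- function(values) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, values)
}

stage_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full CNV-calling pipeline
#'
#' Stages: depth of coverage (or a precomputed coverage table) -> region QC
#' -> background selection -> per-region independent normalization (or the
#' global baseline) -> segmentation and CNV calling. Every intermediate is
#' persisted to `out_dir` (`coverage.tsv`, `qc.tsv`, `qc_report.tsv`,
#' `neighbors.tsv`, `normalized.tsv`, `calls.tsv`, `calls.bed`, `manifest.tsv`)
#' so any stage can be re-run in isolation. Re-running with identical inputs
#' and config is byte-identical, independent of `workers`.
#'
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param coverage_tsv precomputed coverage table (alternative to `bams`).
#' @param bams,targets_bed,fasta BAM paths + BED targets + reference FASTA
#'   (alternative to `coverage_tsv`; `targets_bed` is also used for
#'   coordinates when a coverage table is given, optional there).
#' @param mappability_tsv optional per-region mappability table.
#' @param gc optional per-region GC vector (overrides FASTA computation;
#'   useful for simulated cohorts).
#' @return invisibly, a list with the final `calls` data.frame and the paths
#'   of all artifacts.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         coverage_tsv = NULL, bams = NULL,
                         targets_bed = NULL, fasta = NULL,
                         mappability_tsv = NULL, gc = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  manifest <- c(sprintf("knncnv_version\t%s",
                        as.character(utils::packageVersion("knncnv"))),
                sprintf("config_%s\t%s", names(config),
                        vapply(config, function(v) paste(format(v), collapse = ","), "")))

  # --- stage 1: coverage -----------------------------------------------
  stage_log("stage coverage")
  if (!is.null(coverage_tsv)) {
    mat <- read_coverage_tsv(coverage_tsv)
    if (!is.null(targets_bed)) {
      regions <- load_targets(targets_bed)
      if (!identical(regions$region_id, mat$region_ids))
        stop("targets BED and coverage table regions disagree")
    } else {
      regions <- regions_from_ids(mat$region_ids)
    }
  } else {
    if (is.null(bams) || is.null(targets_bed))
      stop("provide either coverage_tsv or bams + targets_bed")
    regions <- load_targets(targets_bed)
    filt <- read_filter(config$min_mapq, config$include_duplicates,
                        config$include_secondary, config$include_qcfail)
    mat <- build_coverage_matrix(bams, regions, filt)
  }
  paths$coverage <- file.path(out_dir, "coverage.tsv")
  write_coverage_tsv(mat, paths$coverage)

  # --- stage 2: qc ------------------------------------------------------
  stage_log("stage qc (", nrow(mat$counts), " regions, ",
            ncol(mat$counts), " samples)")
  if (is.null(gc)) {
    gc <- if (!is.null(fasta)) annotate_gc(regions, fasta)
          else rep(0.5, nrow(regions))  # neutral: GC filter passes vacuously
  }
  mapp <- load_mappability(mappability_tsv, regions)
  ann <- annotate_regions(regions, mat, gc = gc, mappability = mapp)
  th <- qc_thresholds(config$gc_min, config$gc_max, config$mappability_min,
                      config$median_depth_min, config$median_depth_max,
                      config$length_min, config$length_max)
  qc <- apply_qc(mat, ann, th)
  paths$qc <- file.path(out_dir, "qc.tsv")
  paths$qc_report <- file.path(out_dir, "qc_report.tsv")
  write_coverage_tsv(qc$matrix, paths$qc)
  utils::write.table(qc$result, paths$qc_report, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- stage 3: background selection -----------------------------------
  lcfg <- latent_config(config$K, config$K_max, config$max_iter, config$tol,
                        config$pseudocount)
  if (config$mode == "global") {
    stage_log("stage normalization (global baseline)")
    norm <- normalize_global(qc$matrix, qc$annotations, lcfg)
    paths$neighbors <- NULL
  } else {
    stage_log("stage background selection (", config$mode, ", k = ",
              config$k, ")")
    nb <- select_neighbors(qc$matrix, qc$annotations, config$mode,
                           config$k, config$seed)
    paths$neighbors <- file.path(out_dir, "neighbors.tsv")
    write_neighbors_tsv(nb, qc$matrix$region_ids, paths$neighbors)
    stage_log("stage normalization (", nrow(qc$matrix$counts),
              " independent fits, ", config$workers, " worker(s))")
    norm <- normalize_region_independent(qc$matrix, qc$annotations, nb,
                                         lcfg, workers = config$workers)
  }
  paths$normalized <- file.path(out_dir, "normalized.tsv")
  write_matrix_tsv(round(norm$lambda, 6), paths$normalized)

  # --- stage 4: segmentation & calling ---------------------------------
  stage_log("stage segmentation & calling")
  calls <- call_cnvs(qc$matrix, norm, qc$annotations,
                     alpha = config$alpha, n_perm = config$n_perm,
                     min_width = config$min_width, seed = config$seed,
                     max_gap_bp = config$max_gap_bp,
                     pseudocount = config$pseudocount)
  paths$calls <- file.path(out_dir, "calls.tsv")
  paths$bed <- file.path(out_dir, "calls.bed")
  write_calls_tsv(calls, paths$calls)
  write_calls_bed(calls, paths$bed)

  paths$manifest <- file.path(out_dir, "manifest.tsv")
  writeLines(c(manifest, sprintf("n_regions_input\t%d", nrow(mat$counts)),
               sprintf("n_regions_kept\t%d", nrow(qc$matrix$counts)),
               sprintf("n_calls\t%d", nrow(calls)),
               "status\tok"),
             paths$manifest)
  stage_log("done: ", nrow(calls), " call(s)")
  invisible(list(calls = calls, paths = paths))
}

# reconstruct a targets data.frame from "chrom:start-end" region ids
regions_from_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("region_id not of the form chrom:start-end: ", ids[bad[1L]])
  data.frame(chrom = vapply(m, `[[`, "", 2L),
             start = as.integer(vapply(m, `[[`, "", 3L)),
             end = as.integer(vapply(m, `[[`, "", 4L)),
             region_id = ids, stringsAsFactors = FALSE)
}
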