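#' QC thresholds for sequencing regions
#'
#' The four standard exome-CNV quality filters. A region is kept iff
#' `gc_min <= gc <= gc_max`, `mappability >= mappability_min`,
#' `median_depth_min <= median depth <= median_depth_max` and
#' `length_min <= length <= length_max`. Removal is strict ("below" /
#' "greater than"), so boundary values are kept.
#'
#' @param gc_min,gc_max GC-fraction bounds (default 0.20, 0.80).
#' @param mappability_min minimum mappability (default 0.9).
#' @param median_depth_min,median_depth_max bounds on the per-region median
#'   read depth across samples (default 20, 4000).
#' @param length_min,length_max region length bounds in bp (default 20, 2000).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(gc_min = 0.20, gc_max = 0.80,
                          mappability_min = 0.9,
                          median_depth_min = 20, median_depth_max = 4000,
                          length_min = 20, length_max = 2000) {
  th <- list(gc_min = gc_min, gc_max = gc_max,
             mappability_min = mappability_min,
             median_depth_min = median_depth_min,
             median_depth_max = median_depth_max,
             length_min = length_min, length_max = length_max)
  stopifnot(th$gc_min < th$gc_max,
            th$median_depth_min < th$median_depth_max,
            th$length_min < th$length_max)
  structure(th, class = "qc_thresholds")
}

#' GC fraction of target regions from a reference FASTA
#'
#' `gc = (#G + #C) / (#non-N bases)` over `[start, end)`, case-insensitive.
#' A region made entirely of N has undefined GC and is returned as `NA`
#' (it then automatically fails the GC filter).
#'
#' @param regions data.frame from [load_targets()].
#' @param fasta_path path to an indexed FASTA (a `.fai` is created if absent).
#' @return numeric vector of GC fractions (NA where undefined).
#' @export
annotate_gc <- function(regions, fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA not found: ", fasta_path)
  if (!file.exists(paste0(fasta_path, ".fai")))
    Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  fa_chroms <- as.character(GenomicRanges::seqnames(Rsamtools::scanFaIndex(fa)))
  missing_chr <- setdiff(unique(regions$chrom), fa_chroms)
  if (length(missing_chr))
    stop("chromosome(s) missing from FASTA: ", paste(missing_chr, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  seqs <- Rsamtools::scanFa(fa, gr)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt, NA_real_)
  as.numeric(gc)
}

#' Load per-region mappability values
#'
#' Mappability estimation itself is out of scope; values are user-supplied as
#' a two-column TSV `region_id<TAB>value`. With no file every region gets 1.0
#' (the mappability filter then passes vacuously); regions absent from the
#' file get 1.0 with a warning.
#'
#' @param path TSV path or `NULL`.
#' @param regions data.frame from [load_targets()].
#' @return numeric vector in `[0, 1]`, one value per region.
#' @export
load_mappability <- function(path = NULL, regions) {
  mapp <- rep(1.0, nrow(regions))
  if (is.null(path)) {
    message("no mappability file given; assuming mappability 1.0 everywhere")
    return(mapp)
  }
  if (!file.exists(path)) stop("mappability file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("mappability TSV needs 2 columns: region_id, value")
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(vals)) stop("non-numeric mappability value: ", tab[[2L]][which(is.na(vals))[1L]])
  if (any(vals < 0 | vals > 1))
    stop("mappability outside [0,1]: ", vals[which(vals < 0 | vals > 1)[1L]])
  idx <- match(regions$region_id, tab[[1L]])
  hit <- !is.na(idx)
  mapp[hit] <- vals[idx[hit]]
  if (!all(hit))
    warning(sum(!hit), " region(s) missing from mappability file; assuming 1.0")
  mapp
}

#' Assemble per-region annotations
#'
#' @param regions data.frame from [load_targets()].
#' @param mat a [coverage_matrix()] aligned with `regions` (for median depth).
#' @param gc GC fractions (see [annotate_gc()]); defaults to NA.
#' @param mappability per-region mappability; defaults to 1.0.
#' @return data.frame: region_id, chrom, start, end, gc, mappability, length,
#'   median_depth.
#' @export
annotate_regions <- function(regions, mat, gc = NULL, mappability = NULL) {
  stopifnot(identical(regions$region_id, mat$region_ids))
  if (is.null(gc)) gc <- rep(NA_real_, nrow(regions))
  if (is.null(mappability)) mappability <- rep(1.0, nrow(regions))
  data.frame(region_id = regions$region_id,
             chrom = regions$chrom, start = regions$start, end = regions$end,
             gc = gc, mappability = mappability,
             length = regions$end - regions$start,
             median_depth = apply(mat$counts, 1L, stats::median),
             stringsAsFactors = FALSE)
}

#' Apply region quality control
#'
#' Removes regions failing any of the four filters in [qc_thresholds()];
#' boundary values are kept. Row order of survivors is preserved. Undefined
#' (NA) GC fails the GC filter.
#'
#' @param mat a [coverage_matrix()].
#' @param annotations data.frame from [annotate_regions()], aligned with rows
#'   of `mat`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `matrix` (filtered [coverage_matrix()]), `annotations`
#'   (filtered), and `result`: a data.frame with one row per input region
#'   (`region_id`, `kept`, `reasons` — comma-separated violated filters).
#' @export
apply_qc <- function(mat, annotations, thresholds = qc_thresholds()) {
  stopifnot(identical(annotations$region_id, mat$region_ids))
  th <- thresholds
  fail <- cbind(
    gc = is.na(annotations$gc) |
      annotations$gc < th$gc_min | annotations$gc > th$gc_max,
    mappability = annotations$mappability < th$mappability_min,
    median_depth = annotations$median_depth < th$median_depth_min |
      annotations$median_depth > th$median_depth_max,
    length = annotations$length < th$length_min |
      annotations$length > th$length_max)
  reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ","))
  kept <- !apply(fail, 1L, any)
  if (!any(kept)) stop("empty matrix after QC: every region failed")
  result <- data.frame(region_id = annotations$region_id,
                       gc = annotations$gc,
                       mappability = annotations$mappability,
                       length = annotations$length,
                       median_depth = annotations$median_depth,
                       kept = as.integer(kept),
                       reasons = reasons,
                       stringsAsFactors = FALSE)
  list(matrix = coverage_matrix(mat$counts[kept, , drop = FALSE]),
       annotations = annotations[kept, , drop = FALSE],
       result = result)
}

#' Flag anomalous samples (report only, never removed)
#'
#' Samples whose total coverage lies more than `n_mad`
#' median-absolute-deviations from the cohort median are flagged. No sample
#' is ever removed automatically: no published removal rule exists, so the
#' decision is left to the analyst.
#'
#' @param mat a [coverage_matrix()].
#' @param n_mad flagging threshold in MADs (default 3).
#' @return data.frame: sample_id, total, flagged.
#' @export
flag_samples <- function(mat, n_mad = 3) {
  totals <- colSums(mat$counts)
  med <- stats::median(totals)
  mad <- stats::mad(totals)
  flagged <- if (mad > 0) abs(totals - med) > n_mad * mad else rep(FALSE, length(totals))
  data.frame(sample_id = mat$sample_ids, total = as.numeric(totals),
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}
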