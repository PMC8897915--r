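#' Coverage matrix container
#'
#' A coverage matrix holds raw read counts for `n` sequencing regions (rows)
#' across `m` samples (columns). Counts are non-negative integers; row names
#' are region identifiers of the form `"chrom:start-end"` (0-based half-open
#' coordinates), column names are sample identifiers.
#'
#' @param counts numeric/integer matrix of non-negative whole numbers with
#'   unique row and column names.
#' @return An object of class `coverage_matrix`: a list with elements
#'   `counts` (integer matrix), `region_ids` and `sample_ids`.
#' @export
coverage_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no regions: coverage matrix must have >= 1 row")
  if (ncol(counts) == 0L) stop("no samples: coverage matrix must have >= 1 column")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("coverage matrix needs region_ids as rownames and sample_ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated region_ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample_ids")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 region_ids = rownames(counts),
                 sample_ids = colnames(counts)),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("coverage_matrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: %s\n", format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$counts)

region_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Load target (capture) regions from a BED file
#'
#' Reads a BED3+ file (tab-separated, 0-based half-open). Regions are sorted
#' by (chrom, start, end); exact duplicates are dropped with a warning.
#'
#' @param bed_path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `region_id`.
#' @export
load_targets <- function(bed_path) {
  if (!file.exists(bed_path)) stop("targets file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) stop("no regions in ", bed_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L))
    stop("malformed BED line ", which(n_fields < 3L)[1L], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start_c <- vapply(fields, `[[`, "", 2L)
  end_c <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_c))
  end <- suppressWarnings(as.integer(end_c))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": non-integer coordinates '",
         start_c[bad[1L]], "', '", end_c[bad[1L]], "'")
  bad <- which(end <= start | start < 0L)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": need 0 <= start < end, got ",
         start[bad[1L]], ", ", end[bad[1L]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate region(s) removed from ", bed_path)
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df$region_id <- region_id(df$chrom, df$start, df$end)
  if (anyDuplicated(df$region_id))
    stop("duplicated region_id after load; identical coordinates repeated")
  df
}

#' Read-counting filter
#'
#' Which alignments count towards region depth. Defaults follow common
#' read-depth CNV practice: primary, non-duplicate, QC-pass alignments with
#' mapping quality at least 20. Supplementary alignments are always excluded.
#'
#' @param min_mapq minimum MAPQ (inclusive). MAPQ 255 ("unavailable") passes.
#' @param include_duplicates,include_secondary,include_qcfail include reads
#'   with the corresponding SAM flag set.
#' @return list of class `read_filter`.
#' @export
read_filter <- function(min_mapq = 20L, include_duplicates = FALSE,
                        include_secondary = FALSE, include_qcfail = FALSE) {
  min_mapq <- as.integer(min_mapq)
  stopifnot(length(min_mapq) == 1L, min_mapq >= 0L)
  structure(list(min_mapq = min_mapq,
                 include_duplicates = isTRUE(include_duplicates),
                 include_secondary = isTRUE(include_secondary),
                 include_qcfail = isTRUE(include_qcfail)),
            class = "read_filter")
}

filter_to_param <- function(filter, which) {
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (filter$include_secondary) NA else FALSE,
    isDuplicate = if (filter$include_duplicates) NA else FALSE,
    isNotPassingQualityControls = if (filter$include_qcfail) NA else FALSE,
    isSupplementaryAlignment = FALSE)
  Rsamtools::ScanBamParam(which = which, flag = flag,
                          mapqFilter = filter$min_mapq)
}

#' Count reads per target region for one BAM ("events" counting)
#'
#' A read is counted in every region its aligned reference span
#' `[aln_start, aln_end)` overlaps by at least one base; only the endpoints
#' of the alignment are used, never per-base pileup. A read overlapping two
#' regions contributes to both.
#'
#' @param bam_path path to an indexed BAM file.
#' @param regions data.frame as returned by [load_targets()].
#' @param filter a [read_filter()].
#' @return integer vector of length `nrow(regions)`.
#' @export
count_region_coverage <- function(bam_path, regions, filter = read_filter()) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- paste0(bam_path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", bam_path)
  if (!file.exists(bai) && !file.exists(bai2))
    stop("BAM index missing for ", bam_path,
         "; index it first (e.g. samtools index)")
  bf <- Rsamtools::BamFile(bam_path)
  hdr_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  present <- regions$chrom %in% hdr_chroms
  counts <- integer(nrow(regions))
  if (!all(present)) {
    missing_chr <- unique(regions$chrom[!present])
    warning("chromosome(s) absent from BAM header of ", basename(bam_path),
            ": ", paste(missing_chr, collapse = ", "),
            "; their regions get count 0")
  }
  if (any(present)) {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom[present],
      ranges = IRanges::IRanges(start = regions$start[present] + 1L,
                                end = regions$end[present]))
    res <- Rsamtools::countBam(bf, param = filter_to_param(filter, gr))
    counts[present] <- res$records
  }
  counts
}

#' Build the raw coverage matrix from several BAM files
#'
#' Column `j` is [count_region_coverage()] on BAM `j`; columns are therefore
#' independent of one another. Sample ids are the BAM basenames (extension
#' stripped); name collisions get an ordinal suffix.
#'
#' @param bam_paths character vector of indexed BAM paths.
#' @param regions data.frame from [load_targets()].
#' @param filter a [read_filter()].
#' @return a [coverage_matrix()].
#' @export
build_coverage_matrix <- function(bam_paths, regions, filter = read_filter()) {
  stopifnot(length(bam_paths) >= 1L)
  ids <- tools::file_path_sans_ext(basename(bam_paths))
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  if (any(duplicated(ids)))
    ids[dup] <- paste0(ids[dup], "_", seq_along(ids)[dup])
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(bam_paths),
                   dimnames = list(regions$region_id, ids))
  for (j in seq_along(bam_paths)) {
    counts[, j] <- tryCatch(
      count_region_coverage(bam_paths[j], regions, filter),
      error = function(e) stop("failed to count BAM '", bam_paths[j], "': ",
                               conditionMessage(e), call. = FALSE))
  }
  coverage_matrix(counts)
}

#' Read / write a coverage matrix as TSV
#'
#' The layout is a header line `region_id<TAB>sample1<TAB>...` followed by one
#' row per region. `read_coverage_tsv(write_coverage_tsv(m))` is bit-exact for
#' integer matrices. The same layout with real-valued cells is used for
#' normalized matrices (see `read_matrix_tsv`).
#'
#' @param path TSV file path.
#' @return a [coverage_matrix()].
#' @export
read_coverage_tsv <- function(path) {
  m <- read_matrix_tsv(path)
  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer cell at region '", rownames(m)[bad[1L, 1L]],
         "', sample '", colnames(m)[bad[1L, 2L]], "': ", m[bad[1L, , drop = FALSE]])
  coverage_matrix(m)
}

#' @rdname read_coverage_tsv
#' @param mat a [coverage_matrix()] (or plain named matrix for
#'   `write_matrix_tsv`).
#' @export
write_coverage_tsv <- function(mat, path) {
  if (inherits(mat, "coverage_matrix")) mat <- mat$counts
  write_matrix_tsv(mat, path)
}

#' @rdname read_coverage_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no regions in ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || header[1L] != "region_id")
    stop("malformed header in ", path, ": expected 'region_id<TAB>sample...'")
  samples <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ragged <- which(lengths(rows) != length(header))
  if (length(ragged))
    stop("ragged row ", ragged[1L] + 1L, " in ", path, ": expected ",
         length(header), " fields, got ", lengths(rows)[ragged[1L]])
  ids <- vapply(rows, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(samples))))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("unparseable cell at row '", ids[bad[1L, 1L]], "', column '",
         samples[bad[1L, 2L]], "' in ", path)
  dimnames(vals) <- list(ids, samples)
  vals
}

#' @rdname read_coverage_tsv
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- function(x) {
    if (is.integer(x) || all(x == round(x))) format(x, scientific = FALSE, trim = TRUE)
    else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], fmt(mat[i, ])), collapse = "\t"), "")
  writeLines(c(paste(c("region_id", colnames(mat)), collapse = "\t"), body), path)
  invisible(path)
}
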