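# Shared fixtures and independent oracles.

# tiny coverage_matrix from a plain matrix
cm <- function(y, prefix = "chr1") {
  n <- nrow(y)
  start <- (seq_len(n) - 1L) * 1000L
  rownames(y) <- sprintf("%s:%d-%d", prefix, start, start + 200L)
  colnames(y) <- sprintf("S%03d", seq_len(ncol(y)))
  coverage_matrix(y)
}

regions_for <- function(mat) {
  knncnv:::regions_from_ids(mat$region_ids)
}

# --- independent oracle: per-read overlap scan over SAM text ---------------
# Parses SAM lines directly (no Rsamtools) and counts, for each region, the
# reads whose reference span [pos, pos + cigar_ref_len) overlaps it by >= 1
# bp under the given filter. This is the naive "pileup-style" scan the
# events-based counter must agree with.
cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
}

oracle_counts_sam <- function(sam_lines, regions, min_mapq = 20L,
                              include_duplicates = FALSE,
                              include_secondary = FALSE,
                              include_qcfail = FALSE) {
  recs <- sam_lines[!startsWith(sam_lines, "@")]
  counts <- integer(nrow(regions))
  for (rec in recs) {
    f <- strsplit(rec, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2]); chrom <- f[3]
    pos0 <- as.integer(f[4]) - 1L  # SAM is 1-based
    mapq <- as.integer(f[5])
    if (bitwAnd(flag, 4L) != 0L) next                         # unmapped
    if (!include_secondary && bitwAnd(flag, 256L) != 0L) next
    if (bitwAnd(flag, 2048L) != 0L) next                      # supplementary
    if (!include_duplicates && bitwAnd(flag, 1024L) != 0L) next
    if (!include_qcfail && bitwAnd(flag, 512L) != 0L) next
    if (mapq != 255L && mapq < min_mapq) next
    span_end <- pos0 + cigar_ref_len(f[6])
    hit <- regions$chrom == chrom & regions$start < span_end &
      regions$end > pos0
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# random mini-SAM over the given contigs; returns the SAM lines
random_sam <- function(contigs, n_reads, seed) {
  set.seed(seed)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  chrom <- sample(names(contigs), n_reads, replace = TRUE)
  len <- sample(30:150, n_reads, replace = TRUE)
  pos0 <- vapply(seq_len(n_reads), function(i)
    sample.int(contigs[[chrom[i]]] - len[i], 1L) - 1L, 0L)
  mapq <- sample(c(0L, 10L, 20L, 30L, 60L), n_reads, replace = TRUE)
  flag <- sample(c(0L, 16L, 1024L, 256L, 512L), n_reads, replace = TRUE,
                 prob = c(.4, .3, .1, .1, .1))
  o <- order(chrom, pos0)
  recs <- sprintf("q%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(n_reads), flag[o], chrom[o], pos0[o] + 1L, mapq[o],
                  len[o],
                  vapply(len[o], function(l) strrep("A", l), ""))
  c(header, recs)
}

sam_to_bam <- function(sam_lines, stem) {
  sam <- paste0(stem, ".sam")
  writeLines(sam_lines, sam)
  bam <- Rsamtools::asBam(sam, stem, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

# random target set over contigs (may overlap)
random_targets <- function(contigs, n_regions, seed) {
  set.seed(seed)
  chrom <- sample(names(contigs), n_regions, replace = TRUE)
  start <- vapply(seq_len(n_regions), function(i)
    sample.int(contigs[[chrom[i]]] - 250L, 1L) - 1L, 0L)
  len <- sample(50:200, n_regions, replace = TRUE)
  df <- data.frame(chrom = chrom, start = start, end = start + len,
                   stringsAsFactors = FALSE)
  df <- unique(df[order(df$chrom, df$start, df$end), ])
  rownames(df) <- NULL
  df$region_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df
}

# brute-force kNN oracles ---------------------------------------------------
brute_pearson <- function(y, k) {
  n <- nrow(y)
  rows <- lapply(seq_len(n), function(i) {
    cc <- vapply(seq_len(n), function(j) {
      if (j == i) return(-Inf)
      v <- suppressWarnings(stats::cor(y[i, ], y[j, ]))
      if (is.na(v)) 0 else v
    }, 0)
    order(-cc, seq_len(n))[seq_len(k)]
  })
  matrix(as.integer(unlist(rows)), nrow = n, ncol = k, byrow = TRUE)
}

brute_scalar <- function(values, k) {
  n <- length(values)
  rows <- lapply(seq_len(n), function(i) {
    d <- abs(values - values[i]); d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
  matrix(as.integer(unlist(rows)), nrow = n, ncol = k, byrow = TRUE)
}
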