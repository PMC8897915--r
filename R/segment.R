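#' Raw/normalized coverage ratio track for one sample
#'
#' `r_i = (Y_i + c) / (lambda_i + c)` with pseudocount `c`; segmentation acts
#' on `log2(r_i)` so deletions and duplications are treated symmetrically.
#' Regions are ordered by (chrom, start).
#'
#' @param raw_col integer vector of raw counts for one sample.
#' @param norm_col matching vector of normalized (expected) coverage, > 0.
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`
#'   aligned with the columns.
#' @param pseudocount `c` (default 0.5).
#' @param sample_id label carried through to segments and calls.
#' @return data.frame of class `ratio_track`: region_id, chrom, start, end,
#'   raw, norm, ratio, log2_ratio, sorted by (chrom, start), plus the
#'   original row index in `idx`.
#' @export
compute_ratio_track <- function(raw_col, norm_col, regions,
                                pseudocount = 0.5, sample_id = "sample") {
  if (length(raw_col) != length(norm_col) ||
      length(raw_col) != nrow(regions))
    stop("raw, normalized and region vectors have mismatched lengths")
  stopifnot(all(norm_col > 0))
  tr <- data.frame(region_id = regions$region_id,
                   chrom = regions$chrom,
                   start = regions$start, end = regions$end,
                   raw = as.numeric(raw_col), norm = as.numeric(norm_col),
                   stringsAsFactors = FALSE)
  tr$ratio <- (tr$raw + pseudocount) / (tr$norm + pseudocount)
  tr$log2_ratio <- log2(tr$ratio)
  tr <- tr[order(tr$chrom, tr$start, tr$end), , drop = FALSE]
  tr$idx <- seq_len(nrow(tr))
  attr(tr, "sample_id") <- sample_id
  class(tr) <- c("ratio_track", "data.frame")
  tr
}

# Most aberrant circular arc of x: maximize |T| over arcs (a, b] where
# T = (mean_in - mean_out) / (sd * sqrt(1/n_in + 1/n_out)) with sd the
# overall standard deviation of x (permutation-invariant). Returns the
# two-sided split points and the statistic; ties resolved to the first
# (smallest a, then smallest b) arc for reproducibility.
max_arc_stat <- function(x, min_width = 1L) {
  L <- length(x)
  if (L < 2L * min_width || L < 2L) return(list(stat = 0, a = 0L, b = L))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(list(stat = 0, a = 0L, b = L))
  cs <- c(0, cumsum(x))
  tot <- cs[L + 1L]
  # arcs (a, b], 0 <= a < b <= L, widths in [min_width, L - min_width]
  stat_best <- -Inf; a_best <- 0L; b_best <- L
  for (w in seq.int(min_width, L - min_width)) {
    a <- 0:(L - w)
    sum_in <- cs[a + w + 1L] - cs[a + 1L]
    mean_in <- sum_in / w
    mean_out <- (tot - sum_in) / (L - w)
    stat <- abs(mean_in - mean_out) / (s * sqrt(1 / w + 1 / (L - w)))
    j <- which.max(stat)
    if (stat[j] > stat_best + 1e-12) {
      stat_best <- stat[j]; a_best <- a[j]; b_best <- a[j] + w
    }
  }
  list(stat = stat_best, a = a_best, b = b_best)
}

# Permutation p-value for the max-arc statistic with early termination:
# once `ceiling(alpha * n_perm)` permuted statistics reach the observed one,
# the p-value cannot fall below alpha, so scanning stops.
arc_perm_pvalue <- function(x, observed, alpha, n_perm, min_width) {
  needed <- ceiling(alpha * n_perm)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- max_arc_stat(sample(x), min_width)$stat
    if (perm >= observed) {
      exceed <- exceed + 1L
      if (exceed >= needed) return(exceed / b)  # early stop: p >= alpha
    }
  }
  (exceed + 1L) / (n_perm + 1L)
}

#' Circular binary segmentation of a ratio track
#'
#' Recursive changepoint search per chromosome on the log2 ratio: the most
#' aberrant circular arc (the in-arc vs out-of-arc two-sample t-like
#' statistic) is tested by a seeded permutation test; a significant arc
#' splits the interval at its two boundaries and the pieces are searched
#' recursively. Emitted segments partition each chromosome.
#'
#' @param track a `ratio_track` from [compute_ratio_track()].
#' @param alpha significance level for a split (default 0.01).
#' @param n_perm permutations per test (default 1000).
#' @param min_width minimum regions on each side of a split (default 1).
#' @param seed RNG seed for the permutation test (the global RNG state is
#'   restored afterwards).
#' @return data.frame of segments: sample_id, chrom, first_idx, last_idx
#'   (track row indices, inclusive), start, end (bp), n_exons, raw_sum,
#'   norm_sum, mean_log2_ratio.
#' @export
cbs_segment <- function(track, alpha = 0.01, n_perm = 1000L,
                        min_width = 1L, seed = 1L) {
  stopifnot(nrow(track) >= 1L)
  segments_for <- function(rows) {
    x <- track$log2_ratio[rows]
    L <- length(x)
    out <- list()
    recurse <- function(lo, hi) {   # local 1-based bounds within rows
      L0 <- hi - lo + 1L
      if (L0 >= 2L * min_width && L0 >= 2L) {
        arc <- max_arc_stat(x[lo:hi], min_width)
        if (arc$stat > 0) {
          p <- arc_perm_pvalue(x[lo:hi], arc$stat, alpha, n_perm, min_width)
          if (p < alpha) {
            cuts <- sort(unique(c(arc$a, arc$b)))
            cuts <- cuts[cuts > 0L & cuts < L0]
            bounds <- c(lo - 1L, lo - 1L + cuts, hi)
            for (q in seq_len(length(bounds) - 1L))
              recurse(bounds[q] + 1L, bounds[q + 1L])
            return(invisible())
          }
        }
      }
      out[[length(out) + 1L]] <<- c(lo, hi)
      invisible()
    }
    recurse(1L, L)
    segs <- do.call(rbind, out)
    segs <- segs[order(segs[, 1L]), , drop = FALSE]
    data.frame(first_idx = rows[segs[, 1L]], last_idx = rows[segs[, 2L]])
  }
  res <- with_local_seed(seed, {
    do.call(rbind, lapply(split(seq_len(nrow(track)), track$chrom),
                          segments_for))
  })
  res <- res[order(res$first_idx), , drop = FALSE]
  rownames(res) <- NULL
  data.frame(sample_id = attr(track, "sample_id") %||% "sample",
             chrom = track$chrom[res$first_idx],
             first_idx = res$first_idx, last_idx = res$last_idx,
             start = track$start[res$first_idx],
             end = track$end[res$last_idx],
             n_exons = res$last_idx - res$first_idx + 1L,
             raw_sum = vapply(seq_len(nrow(res)), function(q)
               sum(track$raw[res$first_idx[q]:res$last_idx[q]]), 0),
             norm_sum = vapply(seq_len(nrow(res)), function(q)
               sum(track$norm[res$first_idx[q]:res$last_idx[q]]), 0),
             mean_log2_ratio = vapply(seq_len(nrow(res)), function(q)
               mean(track$log2_ratio[res$first_idx[q]:res$last_idx[q]]), 0),
             stringsAsFactors = FALSE)
}

# Poisson log-likelihood ratio of copy number cn against diploid cn = 2;
# mu floored at the pseudocount so cn = 0 stays finite
segment_lratio <- function(y, lambda, cn, pseudocount) {
  mu_alt <- pmax(cn / 2 * lambda, pseudocount)
  sum(y * log(mu_alt) - mu_alt) - sum(y * log(lambda) - lambda)
}

#' Convert segments into CNV calls
#'
#' Per segment, the copy number is `CN = round(2 * raw_sum / norm_sum)`
#' (half-up); a call is emitted iff `CN != 2`, which implies a no-call band
#' of ratios in `[0.75, 1.25]`. `lratio` is the Poisson log-likelihood ratio
#' of the called copy number against the diploid model; it is reported, not
#' thresholded (note it can be negative just outside the band, where the
#' likelihood still prefers diploid — downstream users may filter on it).
#'
#' @param segments data.frame from [cbs_segment()].
#' @param track the `ratio_track` the segments were computed on.
#' @param pseudocount `c` (default 0.5), used to keep CN = 0 finite.
#' @return data.frame of calls: sample_id, chrom, start, end, type (DEL/DUP),
#'   copy_number, n_exons, raw_sum, norm_sum, ratio, lratio, first_idx,
#'   last_idx.
#' @export
call_segments <- function(segments, track, pseudocount = 0.5) {
  ratio <- segments$raw_sum / segments$norm_sum
  cn <- pmax(round_half_up(2 * ratio), 0)
  keep <- cn != 2
  calls <- segments[keep, c("sample_id", "chrom", "start", "end",
                            "n_exons", "raw_sum", "norm_sum",
                            "first_idx", "last_idx"), drop = FALSE]
  calls$copy_number <- as.integer(cn[keep])
  calls$type <- ifelse(calls$copy_number < 2L, "DEL", "DUP")
  calls$ratio <- ratio[keep]
  calls$lratio <- vapply(which(keep), function(q) {
    rows <- segments$first_idx[q]:segments$last_idx[q]
    segment_lratio(track$raw[rows], track$norm[rows], cn[q], pseudocount)
  }, 0)
  rownames(calls) <- NULL
  calls[, c("sample_id", "chrom", "start", "end", "type", "copy_number",
            "n_exons", "raw_sum", "norm_sum", "ratio", "lratio",
            "first_idx", "last_idx")]
}

#' Merge nearby same-type calls
#'
#' Adjacent calls of the same type in the same sample and chromosome are
#' merged left-to-right when the genomic gap between them is at most
#' `max_gap_bp`; the merged call recomputes its sums, copy number and
#' likelihood ratio over the union of the member exons (intervening
#' diploid regions are not included).
#'
#' @param calls data.frame from [call_segments()].
#' @param track the underlying `ratio_track`.
#' @param max_gap_bp maximum gap in bp (default 50000).
#' @param pseudocount `c` (default 0.5).
#' @return data.frame with the same columns as [call_segments()].
#' @export
merge_calls <- function(calls, track, max_gap_bp = 50000, pseudocount = 0.5) {
  if (nrow(calls) == 0L) return(calls)
  calls <- calls[order(calls$sample_id, calls$chrom, calls$start), , drop = FALSE]
  groups <- split(seq_len(nrow(calls)),
                  paste(calls$sample_id, calls$chrom, sep = "\r"))
  merged <- lapply(groups, function(rows) {
    runs <- list(list(members = rows[1L]))
    for (r in rows[-1L]) {
      cur <- runs[[length(runs)]]
      last <- cur$members[length(cur$members)]
      gap <- calls$start[r] - calls$end[last]
      if (calls$type[r] == calls$type[last] && gap <= max_gap_bp) {
        runs[[length(runs)]]$members <- c(cur$members, r)
      } else {
        runs[[length(runs) + 1L]] <- list(members = r)
      }
    }
    do.call(rbind, lapply(runs, function(run) {
      rs <- run$members
      if (length(rs) == 1L) return(calls[rs, , drop = FALSE])
      exons <- unlist(lapply(rs, function(r)
        calls$first_idx[r]:calls$last_idx[r]))
      raw_sum <- sum(track$raw[exons]); norm_sum <- sum(track$norm[exons])
      cn <- max(round_half_up(2 * raw_sum / norm_sum), 0)
      data.frame(sample_id = calls$sample_id[rs[1L]],
                 chrom = calls$chrom[rs[1L]],
                 start = min(calls$start[rs]), end = max(calls$end[rs]),
                 type = if (cn < 2) "DEL" else "DUP",
                 copy_number = as.integer(cn),
                 n_exons = length(exons),
                 raw_sum = raw_sum, norm_sum = norm_sum,
                 ratio = raw_sum / norm_sum,
                 lratio = segment_lratio(track$raw[exons], track$norm[exons],
                                         cn, pseudocount),
                 first_idx = min(calls$first_idx[rs]),
                 last_idx = max(calls$last_idx[rs]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, merged)
  out <- out[out$copy_number != 2L, , drop = FALSE]  # merge can cancel a call
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call CNVs for every sample of a cohort
#'
#' Runs [compute_ratio_track()], [cbs_segment()], [call_segments()] and
#' [merge_calls()] per sample. Each sample's permutation seed is derived
#' deterministically from `seed` and the sample's column index, so results do
#' not depend on processing order.
#'
#' @param mat raw [coverage_matrix()] (after QC).
#' @param norm a `normalized_matrix` aligned with `mat`.
#' @param regions region data.frame aligned with rows.
#' @param alpha,n_perm,min_width,seed see [cbs_segment()].
#' @param max_gap_bp see [merge_calls()].
#' @param pseudocount shared pseudocount (default 0.5).
#' @return data.frame of calls across all samples (possibly 0 rows).
#' @export
call_cnvs <- function(mat, norm, regions, alpha = 0.01, n_perm = 1000L,
                      min_width = 1L, seed = 1L, max_gap_bp = 50000,
                      pseudocount = 0.5) {
  stopifnot(identical(dim(mat$counts), dim(norm$lambda)))
  res <- lapply(seq_along(mat$sample_ids), function(j) {
    tr <- compute_ratio_track(mat$counts[, j], norm$lambda[, j], regions,
                              pseudocount, sample_id = mat$sample_ids[j])
    segs <- cbs_segment(tr, alpha = alpha, n_perm = n_perm,
                        min_width = min_width,
                        seed = (seed + 7919L * j) %% .Machine$integer.max)
    merge_calls(call_segments(segs, tr, pseudocount), tr,
                max_gap_bp = max_gap_bp, pseudocount = pseudocount)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L)
    out <- data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), type = character(),
                      copy_number = integer(), n_exons = integer(),
                      raw_sum = numeric(), norm_sum = numeric(),
                      ratio = numeric(), lratio = numeric(),
                      first_idx = integer(), last_idx = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write calls as TSV and BED
#'
#' @param calls data.frame of calls.
#' @param path output TSV path.
#' @export
write_calls_tsv <- function(calls, path) {
  cols <- c("sample_id", "chrom", "start", "end", "type", "copy_number",
            "n_exons", "raw_sum", "norm_sum", "ratio", "lratio")
  df <- calls[, cols, drop = FALSE]
  df$ratio <- sprintf("%.6f", df$ratio)
  df$lratio <- sprintf("%.6f", df$lratio)
  df$norm_sum <- sprintf("%.6f", df$norm_sum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_bed <- function(calls, path) {
  lines <- sprintf("%s\t%d\t%d\t%s|%s|%d", calls$chrom, calls$start,
                   calls$end, calls$sample_id, calls$type, calls$copy_number)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
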