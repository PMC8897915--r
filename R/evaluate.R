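#' Evaluate CNV calls against a truth set, with stratification
#'
#' Matching rule: a call is a true positive iff a truth event of the same
#' sample and same type (DEL/DUP) overlaps it by at least one region (exon).
#' Each truth event matches at most one call; assignment is greedy by
#' decreasing exon overlap, ties to the leftmost call. Unmatched calls are
#' false positives, unmatched truth events false negatives.
#'
#' Strata: frequency rare (<= 1%) vs common (> 1%), length short (1-2 exons)
#' vs long (> 2). TP/FN strata come from the matched truth event. FP length
#' strata come from the call's own exon count; FP frequency strata use the
#' call-cohort frequency (fraction of cohort samples with an overlapping
#' same-type call), since false positives have no truth frequency.
#'
#' @param calls data.frame with at least sample_id, type, first_idx,
#'   last_idx (region-index coordinates as produced by [call_cnvs()]).
#' @param truth truth data.frame from [simulate_coverage()] (one row per
#'   carrier per event).
#' @param n_samples cohort size (denominator of frequencies).
#' @param cohort sample ids making up the cohort; defaults to the
#'   simulator's naming `S001..S<n>`. A call from a sample outside the
#'   cohort is an error (truth lists only carriers, so non-carrier cohort
#'   samples are still admissible call sources).
#' @return data.frame of class `evaluation_report`: one row per stratum
#'   (all, rare, common, short, long) with TP, FP, FN, precision,
#'   sensitivity.
#' @export
evaluate_calls <- function(calls, truth, n_samples,
                           cohort = sprintf("S%03d", seq_len(n_samples))) {
  cohort <- union(cohort, truth$sample_id)
  if (nrow(calls) > 0 && any(!calls$sample_id %in% cohort))
    stop("call sample absent from truth cohort: ",
         calls$sample_id[which(!calls$sample_id %in% cohort)[1L]])
  n_calls <- nrow(calls); n_truth <- nrow(truth)
  call_matched <- rep(FALSE, n_calls)
  truth_matched <- rep(FALSE, n_truth)
  truth$match_call <- NA_integer_

  if (n_truth > 0 && n_calls > 0) {
    for (t in order(truth$first_idx)) {
      cand <- which(!call_matched &
                      calls$sample_id == truth$sample_id[t] &
                      calls$type == truth$type[t] &
                      calls$first_idx <= truth$last_idx[t] &
                      calls$last_idx >= truth$first_idx[t])
      if (!length(cand)) next
      ov <- pmin(calls$last_idx[cand], truth$last_idx[t]) -
        pmax(calls$first_idx[cand], truth$first_idx[t]) + 1L
      best <- cand[order(-ov, calls$first_idx[cand])][1L]
      call_matched[best] <- TRUE
      truth_matched[t] <- TRUE
      truth$match_call[t] <- best
    }
  }

  truth_freq_stratum <- ifelse(truth$frequency <= 0.01, "rare", "common")
  truth_len_stratum <- ifelse(truth$n_exons <= 2L, "short", "long")

  # FP strata from the call itself
  fp_idx <- which(!call_matched)
  fp_len <- ifelse(calls$n_exons[fp_idx] <= 2L, "short", "long")
  fp_freq <- vapply(fp_idx, function(ci) {
    sup <- sum(vapply(unique(calls$sample_id), function(s)
      any(calls$sample_id == s & calls$type == calls$type[ci] &
            calls$first_idx <= calls$last_idx[ci] &
            calls$last_idx >= calls$first_idx[ci]), TRUE))
    if (sup / n_samples <= 0.01) "rare" else "common"
  }, "")

  strata <- c("all", "rare", "common", "short", "long")
  rows <- lapply(strata, function(st) {
    in_truth <- if (st == "all") rep(TRUE, n_truth)
      else if (st %in% c("rare", "common")) truth_freq_stratum == st
      else truth_len_stratum == st
    in_fp <- if (st == "all") rep(TRUE, length(fp_idx))
      else if (st %in% c("rare", "common")) fp_freq == st
      else fp_len == st
    tp <- sum(truth_matched & in_truth)
    fn <- sum(!truth_matched & in_truth)
    fp <- sum(in_fp)
    data.frame(stratum = st, TP = tp, FP = fp, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("CNV evaluation (TP matched on >= 1 shared exon, same sample & type)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report as TSV
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_report_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# TP: >= 1 shared exon, same sample and type; 1-1 greedy by overlap",
    "# FP frequency stratum from call-cohort frequency (no truth frequency exists for FPs)"),
    con)
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
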