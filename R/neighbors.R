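#' Background-region selection (kNN and alternatives)
#'
#' For every sequencing region a set of `k` other regions is chosen to model
#' the background during normalization. The primary mode ranks candidates by
#' Pearson correlation of the depth-of-coverage profiles across samples;
#' alternative modes used for comparison are uniform random selection and
#' nearest-by-scalar-metric (GC fraction, region length, mean depth).
#'
#' All modes exclude the region itself, return exactly `min(k, n-1)`
#' neighbors per region, and break ties by ascending region index so that
#' results are bit-reproducible.
#'
#' @name background_selection
NULL

new_neighbor_assignment <- function(indices, scores, mode) {
  stopifnot(is.matrix(indices))
  structure(list(indices = indices, scores = scores, mode = mode),
            class = "neighbor_assignment")
}

#' @export
print.neighbor_assignment <- function(x, ...) {
  cat(sprintf("neighbor_assignment (%s): %d regions, k = %d\n",
              x$mode, nrow(x$indices), ncol(x$indices)))
  invisible(x)
}

clip_k <- function(k, n) {
  stopifnot(length(k) == 1L, k >= 1L)
  if (k > n - 1L) {
    warning("k = ", k, " exceeds n - 1 = ", n - 1L, "; clipped")
    k <- n - 1L
  }
  as.integer(k)
}

#' Pearson-correlation k nearest neighbors
#'
#' For each region `i`, selects the `k` regions whose raw count rows are most
#' positively Pearson-correlated with row `i` across samples. Zero-variance
#' rows have undefined correlation and are treated as correlation 0 against
#' everything; ties break by ascending index.
#'
#' @param mat a [coverage_matrix()] with at least 3 samples.
#' @param k number of background regions per region.
#' @param log1p correlate `log1p(counts)` instead of raw counts
#'   (off by default; raw counts are the literal reading of the method).
#' @return a `neighbor_assignment`: `indices` is an `n x k` matrix whose row
#'   `i` lists neighbor indices in decreasing-correlation order, `scores` the
#'   matching correlations.
#' @export
pearson_neighbors <- function(mat, k, log1p = FALSE) {
  y <- mat$counts
  n <- nrow(y); m <- ncol(y)
  if (m < 3L) stop("too few samples for correlation (need >= 3, got ", m, ")")
  if (n < 2L) stop("need >= 2 regions")
  k <- clip_k(k, n)
  x <- if (log1p) log1p(y) else y
  cc <- suppressWarnings(stats::cor(t(x)))  # n x n; NA for zero-variance rows
  cc[!is.finite(cc)] <- 0
  diag(cc) <- -Inf
  idx <- matrix(0L, n, k)
  sc <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    o <- order(-cc[i, ], seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    sc[i, ] <- cc[i, o]
  }
  new_neighbor_assignment(idx, sc, "pearson")
}

#' Nearest neighbors by a scalar region metric
#'
#' For each region `i`, the `k` regions minimizing `|values[j] - values[i]|`;
#' ties by ascending index. Used with `values` = GC fraction, region length,
#' or per-region mean depth.
#'
#' @param values finite numeric vector, one value per region.
#' @param k number of background regions.
#' @param region_ids optional ids used in error messages.
#' @return a `neighbor_assignment` (scores are the absolute differences).
#' @export
scalar_neighbors <- function(values, k, region_ids = NULL) {
  n <- length(values)
  bad <- which(!is.finite(values))
  if (length(bad)) {
    lab <- if (!is.null(region_ids)) region_ids[bad[1L]] else bad[1L]
    stop("non-finite metric for region ", lab)
  }
  if (n < 2L) stop("need >= 2 regions")
  k <- clip_k(k, n)
  idx <- matrix(0L, n, k)
  sc <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d <- abs(values - values[i])
    d[i] <- Inf
    o <- order(d, seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    sc[i, ] <- d[o]
  }
  new_neighbor_assignment(idx, sc, "scalar")
}

#' Uniform random background selection
#'
#' Each region draws `k` indices uniformly without replacement from the other
#' regions; draws are independent across regions and reproducible from
#' `seed`. The global RNG state is left untouched.
#'
#' @param n number of regions.
#' @param k number of background regions.
#' @param seed integer seed.
#' @return a `neighbor_assignment` (scores are NA).
#' @export
random_neighbors <- function(n, k, seed) {
  if (n < 2L) stop("need >= 2 regions")
  k <- clip_k(k, n)
  idx <- with_local_seed(seed, {
    t(vapply(seq_len(n),
             function(i) sample((seq_len(n))[-i], k),
             integer(k)))
  })
  idx <- matrix(as.integer(idx), nrow = n)
  new_neighbor_assignment(idx, matrix(NA_real_, n, k), "random")
}

#' Dispatch on the selection mode
#'
#' @param mat a [coverage_matrix()].
#' @param annotations region annotations (needed for gc/length modes).
#' @param mode one of `"pearson"`, `"random"`, `"gc"`, `"length"`,
#'   `"mean_depth"`.
#' @param k number of background regions.
#' @param seed seed for `"random"` mode.
#' @return a `neighbor_assignment`.
#' @export
select_neighbors <- function(mat, annotations = NULL,
                             mode = c("pearson", "random", "gc", "length",
                                      "mean_depth"),
                             k, seed = 1L) {
  mode <- match.arg(mode)
  switch(mode,
    pearson = pearson_neighbors(mat, k),
    random = random_neighbors(nrow(mat$counts), k, seed),
    gc = scalar_neighbors(annotations$gc, k, annotations$region_id),
    length = scalar_neighbors(annotations$length, k, annotations$region_id),
    mean_depth = scalar_neighbors(rowMeans(mat$counts), k, mat$region_ids))
}

#' Write / read a neighbor assignment as TSV
#'
#' Layout: `region_id<TAB>comma-separated neighbor region_ids` in rank order.
#' @param nb a `neighbor_assignment`.
#' @param region_ids character vector mapping indices to ids.
#' @param path output path.
#' @export
write_neighbors_tsv <- function(nb, region_ids, path) {
  lines <- vapply(seq_len(nrow(nb$indices)), function(i)
    paste(region_ids[i],
          paste(region_ids[nb$indices[i, ]], collapse = ","), sep = "\t"), "")
  writeLines(c("region_id\tneighbors", lines), path)
  invisible(path)
}

#' @rdname write_neighbors_tsv
#' @export
read_neighbors_tsv <- function(path, region_ids) {
  lines <- readLines(path)[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (!identical(ids, region_ids))
    stop("neighbor file region_ids do not match the coverage matrix")
  nbs <- lapply(parts, function(p) {
    j <- match(strsplit(p[2L], ",", fixed = TRUE)[[1L]], region_ids)
    if (anyNA(j)) stop("unknown neighbor region_id in ", path)
    as.integer(j)
  })
  k <- unique(lengths(nbs))
  if (length(k) != 1L) stop("ragged neighbor lists in ", path)
  new_neighbor_assignment(do.call(rbind, nbs),
                          matrix(NA_real_, length(nbs), k), "file")
}
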