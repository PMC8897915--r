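#' Simulation specification for WES-like coverage
#'
#' Describes the generative model the synthetic cohort is drawn from:
#' \deqn{Y_{ij} \sim Poisson(\lambda_{ij}), \quad
#'       \lambda_{ij} = N_j \beta_i e^{f(GC_i)} e^{(GH^T)_{ij}} \cdot cn_{ij}/2}
#' with library-size factors `N_j ~ lognormal(0, libsize_sd)`, capture
#' efficiencies `beta_i ~ Gamma(shape = 10)` scaled to mean `depth_mean`
#' (coefficient of variation about 0.32: capture is uneven, but the named
#' biases — GC, library size, latent factors — dominate unstructured
#' region-to-region spread, the regime a parameter-recovery design needs),
#' a quadratic GC-bias bump `f(gc) = -gc_bias_strength (gc - 0.5)^2`, and
#' `K_true` Gaussian latent factors of scale `factor_scale` emulating batch
#' and capture-kit artifacts. Spiked CNV events multiply `lambda` by
#' `copy_number / 2` over a contiguous run of regions before Poisson
#' sampling, so carriers are true copy-number changes of the expected
#' coverage.
#'
#' @param n_regions,n_samples cohort dimensions.
#' @param seed RNG seed; the draw is fully reproducible from it.
#' @param depth_mean mean reads per region for an average sample
#'   (default 100).
#' @param libsize_sd log-scale sd of library-size factors (default 0.3,
#'   i.e. roughly +-30% library-size variation).
#' @param gc_bias_strength coefficient of the quadratic GC bump (default 8:
#'   about a 40% coverage dip at GC 0.25 or 0.75 relative to GC 0.5, in the
#'   middle of empirically reported exome GC-bias magnitudes).
#' @param K_true number of latent artifact factors (default 0).
#' @param factor_scale scale of the latent loadings (default 0.3 when
#'   `K_true > 0`; entries of `G H^T` then have sd about `factor_scale`).
#' @param cnv_events list of events, each a list with `type` ("DEL"/"DUP"),
#'   `copy_number` (0, 1, 3 or 4), `n_exons` (>= 1) and `carrier_fraction`
#'   in (0, 1].
#' @param region_gap gap in bp between consecutive simulated regions
#'   (default 2000).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_regions = 200L, n_samples = 50L, seed = 1L,
                            depth_mean = 100, libsize_sd = 0.3,
                            gc_bias_strength = 8, K_true = 0L,
                            factor_scale = 0.3, cnv_events = list(),
                            region_gap = 2000L) {
  stopifnot(n_regions >= 2L, n_samples >= 1L, depth_mean > 0,
            libsize_sd >= 0, gc_bias_strength >= 0, K_true >= 0L,
            factor_scale >= 0)
  for (ev in cnv_events) {
    stopifnot(ev$type %in% c("DEL", "DUP"),
              ev$copy_number %in% c(0L, 1L, 3L, 4L),
              (ev$copy_number < 2L) == (ev$type == "DEL"),
              ev$n_exons >= 1L, ev$n_exons <= n_regions,
              ev$carrier_fraction > 0, ev$carrier_fraction <= 1)
  }
  structure(list(n_regions = as.integer(n_regions),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 depth_mean = depth_mean, libsize_sd = libsize_sd,
                 gc_bias_strength = gc_bias_strength,
                 K_true = as.integer(K_true), factor_scale = factor_scale,
                 cnv_events = cnv_events, region_gap = as.integer(region_gap)),
            class = "simulation_spec")
}

#' Convenience constructor for a CNV event
#' @param type "DEL" or "DUP".
#' @param copy_number 0/1 (DEL) or 3/4 (DUP).
#' @param n_exons regions spanned by the event.
#' @param carrier_fraction fraction of samples carrying it; the realized
#'   carrier count is `max(1, round(fraction * n_samples))`.
#' @export
cnv_event <- function(type = c("DEL", "DUP"), copy_number = NULL,
                      n_exons = 3L, carrier_fraction = 0.02) {
  type <- match.arg(type)
  if (is.null(copy_number)) copy_number <- if (type == "DEL") 1L else 3L
  list(type = type, copy_number = as.integer(copy_number),
       n_exons = as.integer(n_exons), carrier_fraction = carrier_fraction)
}

#' Simulate a WES-like coverage matrix with spiked CNVs
#'
#' Draws the cohort described by a [simulation_spec()]. Regions are laid out
#' consecutively on `chr1` with lengths ~ Uniform(100, 500) bp and GC
#' fractions ~ Uniform(0.25, 0.75). Events are placed on contiguous region
#' runs; an event whose carriers would overlap one of their existing events
#' is re-drawn (up to 100 attempts, then an error).
#'
#' @param spec a [simulation_spec()].
#' @return list with `matrix` (a [coverage_matrix()]), `regions` (targets
#'   data.frame), `annotations` (see [annotate_regions()]), `truth` (the
#'   truth set: sample_id, chrom, start, end, type, copy_number, n_exons,
#'   frequency, first_idx, last_idx), `lambda_true` (the CNV-free expected
#'   coverage), `lambda_cnv` (with CNV effects applied), and the drawn
#'   parameters `N`, `beta`, `f_gc`, `G`, `H`.
#' @export
simulate_coverage <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_regions; m <- spec$n_samples
  with_local_seed(spec$seed, {
    lens <- as.integer(round(stats::runif(n, 100, 500)))
    gaps <- rep(spec$region_gap, n)
    start <- cumsum(c(1000L, (lens + gaps)[-n]))
    regions <- data.frame(chrom = "chr1", start = start,
                          end = start + lens,
                          region_id = region_id("chr1", start, start + lens),
                          stringsAsFactors = FALSE)
    gc <- stats::runif(n, 0.25, 0.75)

    N <- exp(stats::rnorm(m, 0, spec$libsize_sd))
    N <- N / exp(mean(log(N)))
    beta <- stats::rgamma(n, shape = 10, rate = 10 / spec$depth_mean)
    beta <- pmax(beta, 1)  # avoid regions that would fail median-depth QC trivially
    f_gc <- -spec$gc_bias_strength * (gc - 0.5)^2
    f_gc <- f_gc - mean(f_gc)
    if (spec$K_true > 0L) {
      G <- matrix(stats::rnorm(n * spec$K_true, 0, sqrt(spec$factor_scale)),
                  n, spec$K_true)
      H <- matrix(stats::rnorm(m * spec$K_true, 0, sqrt(spec$factor_scale)),
                  m, spec$K_true)
    } else {
      G <- matrix(0, n, 0); H <- matrix(0, m, 0)
    }
    lambda_true <- outer(beta * exp(f_gc), N) * exp(G %*% t(H))
    dimnames(lambda_true) <- list(regions$region_id,
                                  sprintf("S%03d", seq_len(m)))

    # spike CNVs multiplicatively
    cn_factor <- matrix(1, n, m)
    truth <- list()
    occupied <- vector("list", m)  # per-sample list of occupied index runs
    for (ev in spec$cnv_events) {
      n_carriers <- max(1L, as.integer(round(ev$carrier_fraction * m)))
      placed <- FALSE
      for (attempt in seq_len(100L)) {
        first <- sample.int(n - ev$n_exons + 1L, 1L)
        run <- first:(first + ev$n_exons - 1L)
        carriers <- sort(sample.int(m, n_carriers))
        clash <- any(vapply(carriers, function(j)
          any(run %in% occupied[[j]]), TRUE))
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place CNV event without overlap after 100 attempts")
      for (j in carriers) {
        occupied[[j]] <- c(occupied[[j]], run)
        cn_factor[run, j] <- ev$copy_number / 2
      }
      freq <- n_carriers / m
      truth[[length(truth) + 1L]] <- data.frame(
        sample_id = sprintf("S%03d", carriers),
        chrom = "chr1",
        start = regions$start[run[1L]],
        end = regions$end[run[length(run)]],
        type = ev$type, copy_number = ev$copy_number,
        n_exons = ev$n_exons, frequency = freq,
        first_idx = run[1L], last_idx = run[length(run)],
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(), chrom = character(),
                 start = integer(), end = integer(), type = character(),
                 copy_number = integer(), n_exons = integer(),
                 frequency = numeric(), first_idx = integer(),
                 last_idx = integer(), stringsAsFactors = FALSE)

    lambda_cnv <- lambda_true * cn_factor
    y <- matrix(stats::rpois(n * m, lambda_cnv), n, m,
                dimnames = dimnames(lambda_true))
    mat <- coverage_matrix(y)
    ann <- annotate_regions(regions, mat, gc = gc,
                            mappability = rep(1.0, n))
    list(matrix = mat, regions = regions, annotations = ann, truth = truth,
         lambda_true = lambda_true, lambda_cnv = lambda_cnv,
         N = N, beta = beta, f_gc = f_gc, G = G, H = H)
  })
}

#' Write the simulator truth set as TSV
#' @param truth truth data.frame from [simulate_coverage()].
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Emit tiny indexed BAM fixtures from explicit read placements
#'
#' Writes one minimal, sorted, indexed BAM per sample whose
#' [count_region_coverage()] output equals the counts implied by the
#' placements — used to test the coverage module without shipping binary
#' files.
#'
#' @param contigs named integer vector of contig lengths.
#' @param placements data.frame with columns `sample`, `chrom`, `aln_start`
#'   (0-based), `aln_end` (exclusive), `mapq`, and optionally `flag`
#'   (SAM flag, default 0).
#' @param out_dir output directory (created if needed).
#' @return named character vector of BAM paths (one per sample).
#' @export
emit_fixture_bams <- function(contigs, placements, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(all(c("sample", "chrom", "aln_start", "aln_end", "mapq") %in%
                  names(placements)))
  bad <- !placements$chrom %in% names(contigs)
  if (any(bad))
    stop("placement on undeclared contig: ", placements$chrom[which(bad)[1L]])
  if (any(placements$aln_end > contigs[placements$chrom]))
    stop("placement beyond declared contig length")
  if (is.null(placements$flag)) placements$flag <- 0L
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                      as.integer(contigs)))
  paths <- character(0)
  for (s in unique(placements$sample)) {
    p <- placements[placements$sample == s, , drop = FALSE]
    p <- p[order(p$chrom, p$aln_start), , drop = FALSE]
    len <- p$aln_end - p$aln_start
    stopifnot(all(len >= 1L))
    recs <- sprintf("r%04d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    seq_len(nrow(p)), p$flag, p$chrom, p$aln_start + 1L,
                    p$mapq, len,
                    vapply(len, function(l)
                      paste(rep("A", l), collapse = ""), ""))
    sam <- file.path(out_dir, paste0(s, ".sam"))
    writeLines(c(header, recs), sam)
    bam <- Rsamtools::asBam(sam, file.path(out_dir, s),
                            overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
    paths[s] <- bam
  }
  paths
}
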