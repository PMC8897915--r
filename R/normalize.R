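#' Configuration of the Poisson log-linear latent-factor model
#'
#' The expected CNV-free coverage is modeled as
#' \deqn{\lambda_{ij} = N_j \, \beta_i \, e^{f(GC_i)} \, e^{(GH^T)_{ij}}}
#' with sample size factors `N_j` (geometric mean fixed to 1), region capture
#' effects `beta_i` (absorbing static region-length effects), a smooth GC-bias
#' curve `f` (mean 0 across regions), and a rank-`K` latent term `G H^T`
#' capturing systematic artifacts not explained by the named covariates.
#' Parameters are estimated by block-coordinate maximum likelihood.
#'
#' @param K latent rank: a non-negative integer, or `"auto"` to select by BIC
#'   (see [select_K()]).
#' @param K_max cap for `"auto"` selection (default 5).
#' @param max_iter iteration cap for the block-coordinate loop (default 100).
#' @param tol relative Poisson-deviance change declaring convergence
#'   (default 1e-6).
#' @param pseudocount constant added inside logarithms (default 0.5).
#' @return list of class `latent_config`.
#' @export
latent_config <- function(K = "auto", K_max = 5L, max_iter = 100L,
                          tol = 1e-6, pseudocount = 0.5) {
  if (!identical(K, "auto")) {
    K <- as.integer(K)
    stopifnot(K >= 0L)
  }
  stopifnot(K_max >= 0L, max_iter >= 1L, tol > 0, pseudocount > 0)
  structure(list(K = K, K_max = as.integer(K_max),
                 max_iter = as.integer(max_iter), tol = tol,
                 pseudocount = pseudocount),
            class = "latent_config")
}

# largest admissible latent rank for an n x m subgroup; small subgroups make
# latent-factor estimation unstable, hence the n/5 cap below 10 regions
latent_rank_cap <- function(n, m, config) {
  cap <- min(config$K_max, min(n, m) - 1L)
  if (n < 10L) cap <- min(cap, floor(n / 5))
  max(cap, 0L)
}

#' Fit the Poisson log-linear latent-factor model
#'
#' Block-coordinate ascent on the Poisson likelihood:
#' \enumerate{
#'   \item `beta_i <- sum_j Y_ij / sum_j N_j e^{f_i} e^{(GH)_ij}` and
#'     `N_j <- sum_i Y_ij / sum_i beta_i e^{f_i} e^{(GH)_ij}` — the exact
#'     conditional MLEs, which can never increase the deviance;
#'   \item the GC curve is re-estimated by local regression (lowess,
#'     span 0.75) of the per-region log residual against GC, re-centered to
#'     mean 0 (the scale is re-absorbed by the following exact `beta` step);
#'   \item the latent term is re-estimated as the rank-`K` truncated SVD of
#'     `L_ij = log((Y_ij + c) / (N_j beta_i e^{f_i} + c))`, with
#'     `G <- U diag(d)` and `H <- V` (orthonormal columns).
#' }
#' Steps 2 and 3 are heuristic refits, so each is accepted only if it does
#' not increase the deviance (otherwise the previous value is kept); the
#' deviance is therefore non-increasing across iterations. Iteration stops
#' when the relative deviance change drops below `tol`.
#'
#' @param counts integer matrix (regions x samples), >= 2 regions,
#'   >= 3 samples, no all-zero sample column.
#' @param gc per-region GC fractions (NULL disables the GC curve).
#' @param lengths per-region lengths (kept in the interface; static length
#'   effects are absorbed by `beta`).
#' @param config a [latent_config()]. `K = "auto"` selects the rank by BIC.
#' @return list of class `normalization_model`: `N`, `beta`, `f_gc`, `G`,
#'   `H`, `K_used`, `converged`, `n_iter`, `deviance`, `loglik`, `lambda`
#'   (the fitted matrix), `zero_rows` (flagged all-zero regions).
#' @export
fit_poisson_latent <- function(counts, gc = NULL, lengths = NULL,
                               config = latent_config()) {
  y <- as.matrix(counts)
  n <- nrow(y); m <- ncol(y)
  if (n < 2L) stop("need >= 2 regions to fit")
  if (m < 3L) stop("need >= 3 samples to fit")
  if (any(colSums(y) == 0))
    stop("all-zero sample column: ", colnames(y)[which(colSums(y) == 0)[1L]])
  if (identical(config$K, "auto")) return(select_K_fit(y, gc, lengths, config))
  K <- min(config$K, latent_rank_cap(n, m, config))
  if (K < config$K && n < 10L)
    warning("subgroup of ", n, " regions is small; latent rank reduced to ", K)
  fit_poisson_latent_fixed(y, gc, K, config)
}

fit_poisson_latent_fixed <- function(y, gc, K, config) {
  n <- nrow(y); m <- ncol(y)
  c0 <- config$pseudocount
  row_tot <- rowSums(y)
  zero_rows <- row_tot == 0

  # --- initialization ---------------------------------------------------
  row_med <- apply(y, 1L, stats::median)
  pos <- row_med > 0
  N <- if (any(pos)) {
    apply(y[pos, , drop = FALSE] / row_med[pos], 2L, stats::median)
  } else colSums(y) / mean(colSums(y))
  N[N <= 0] <- min(N[N > 0], 1)
  N <- N / exp(mean(log(N)))
  beta <- rowMeans(sweep(y, 2L, N, "/"))
  beta[beta <= 0] <- c0 / m
  f <- numeric(n)
  G <- matrix(0, n, max(K, 1L))[, seq_len(K), drop = FALSE]
  H <- matrix(0, m, max(K, 1L))[, seq_len(K), drop = FALSE]

  use_gc <- !is.null(gc) && length(unique(gc[is.finite(gc)])) >= 3L
  if (use_gc) {
    gc_f <- ifelse(is.finite(gc), gc, stats::median(gc, na.rm = TRUE))
  }

  lam <- function(beta, N, f, G, H) {
    outer(beta * exp(f), N) * exp(G %*% t(H))
  }
  exact_beta <- function(N, f, G, H) {
    denom <- exp(f) * (exp(G %*% t(H)) %*% N)
    b <- as.numeric(row_tot / denom)
    b[zero_rows] <- as.numeric(c0 / denom[zero_rows])  # flagged floor
    b
  }

  beta <- exact_beta(N, f, G, H)
  dev <- poisson_deviance(y, lam(beta, N, f, G, H))
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(config$max_iter)) {
    dev_prev <- dev

    # exact conditional MLE blocks
    beta <- exact_beta(N, f, G, H)
    eGH <- exp(G %*% t(H))
    N <- as.numeric(colSums(y) / crossprod(eGH, beta * exp(f)))
    s <- exp(mean(log(N)))
    N <- N / s; beta <- beta * s
    beta <- exact_beta(N, f, G, H)
    dev <- poisson_deviance(y, lam(beta, N, f, G, H))

    # guarded GC-curve refit: the total log row effect log(beta_i) + f_i is
    # identified by the likelihood; its split into a smooth GC component f
    # and a residual capture effect beta is a smoothing convention, so f is
    # the lowess fit of the row effect against GC and beta absorbs the rest
    # (the deviance is unchanged by construction).
    if (use_gc) {
      eGH <- exp(G %*% t(H))
      denom <- as.numeric(eGH %*% N)   # expected row totals sans beta, f
      r <- log((row_tot + c0) / (denom + c0))
      lw <- stats::lowess(gc_f, r, f = 0.75)
      f_new <- stats::approx(lw$x, lw$y, xout = gc_f, rule = 2, ties = mean)$y
      f_new <- f_new - mean(f_new)
      beta_new <- {
        denom2 <- exp(f_new) * as.numeric(eGH %*% N)
        b <- row_tot / denom2; b[zero_rows] <- c0 / denom2[zero_rows]; b
      }
      dev_new <- poisson_deviance(y, lam(beta_new, N, f_new, G, H))
      if (dev_new <= dev) { f <- f_new; beta <- beta_new; dev <- dev_new }
    }

    # guarded latent-factor refit (truncated SVD of log residuals)
    if (K > 0L) {
      base <- outer(beta * exp(f), N)
      L <- log((y + c0) / (base + c0))
      sv <- svd(L, nu = K, nv = K)
      G_new <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
      H_new <- sv$v
      beta_new <- exact_beta(N, f, G_new, H_new)
      dev_new <- poisson_deviance(y, lam(beta_new, N, f, G_new, H_new))
      if (dev_new <= dev) { G <- G_new; H <- H_new; beta <- beta_new; dev <- dev_new }
    }

    if (abs(dev_prev - dev) <= config$tol * max(dev_prev, 1e-8)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("normalization did not converge in ", config$max_iter, " iterations")

  lambda <- lam(beta, N, f, G, H)
  dimnames(lambda) <- dimnames(y)
  structure(list(N = N, beta = beta, f_gc = f, G = G, H = H,
                 K_used = K, converged = converged, n_iter = iter,
                 deviance = dev, loglik = poisson_loglik(y, lambda),
                 lambda = lambda, zero_rows = which(zero_rows)),
            class = "normalization_model")
}

#' Select the latent rank by BIC
#'
#' Fits `K = 0 .. K_max` and returns the rank minimizing
#' `BIC = -2 loglik + K (n + m) log(n m)`. Deterministic.
#'
#' @param counts,gc,lengths,config as in [fit_poisson_latent()].
#' @return integer, the selected rank.
#' @export
select_K <- function(counts, gc = NULL, lengths = NULL,
                     config = latent_config()) {
  select_K_fit(as.matrix(counts), gc, lengths, config)$K_used
}

select_K_fit <- function(y, gc, lengths, config) {
  n <- nrow(y); m <- ncol(y)
  cap <- latent_rank_cap(n, m, config)
  fits <- lapply(0:cap, function(K)
    fit_poisson_latent_fixed(y, gc, K, config))
  bic <- vapply(fits, function(fit)
    -2 * fit$loglik + fit$K_used * (n + m) * log(n * m), 0)
  fits[[which.min(bic)]]
}

new_normalized_matrix <- function(lambda, provenance) {
  stopifnot(all(lambda > 0), all(is.finite(lambda)))
  structure(list(lambda = lambda, provenance = provenance),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d regions x %d samples\n",
              nrow(x$lambda), ncol(x$lambda)))
  invisible(x)
}

#' Global (chromosome-wide) normalization baseline
#'
#' One [fit_poisson_latent()] on the whole matrix — the classical approach
#' that per-region independent normalization is compared against.
#'
#' @param mat a [coverage_matrix()] (after QC).
#' @param annotations aligned region annotations (for GC).
#' @param config a [latent_config()].
#' @return a `normalized_matrix`: `lambda` (strictly positive, same dimnames
#'   as the counts) and per-region `provenance`.
#' @export
normalize_global <- function(mat, annotations = NULL,
                             config = latent_config()) {
  gc <- annotations$gc
  fit <- fit_poisson_latent(mat$counts, gc = gc,
                            lengths = annotations$length, config = config)
  prov <- data.frame(region_id = mat$region_ids,
                     subgroup_size = nrow(mat$counts),
                     K_used = fit$K_used,
                     converged = fit$converged,
                     stringsAsFactors = FALSE)
  new_normalized_matrix(fit$lambda, prov)
}

#' Per-region independent normalization (fork-join)
#'
#' For every region `i` the subgroup `{i} + neighbors(i)` of size `k + 1` is
#' normalized on its own with [fit_poisson_latent()], and only row `i` of the
#' subgroup fit is kept; the `n` single rows are joined into the output
#' matrix. Subgroups are independent tasks, so they may run on several
#' workers; identical subgroup sets are fitted once (the fit depends only on
#' the member set, not on which member is under consideration). The result
#' is bit-identical for any worker count.
#'
#' @param mat a [coverage_matrix()] (after QC).
#' @param annotations aligned region annotations (for GC).
#' @param neighbors a `neighbor_assignment` covering every region of `mat`.
#' @param config a [latent_config()].
#' @param workers parallel workers (forked; 1 = sequential).
#' @return a `normalized_matrix`. Rows whose subgroup fit failed are flagged
#'   in `provenance$failed` and filled with the row-median depth as a
#'   fallback; more than 10% failures aborts.
#' @export
normalize_region_independent <- function(mat, annotations = NULL,
                                         neighbors, config = latent_config(),
                                         workers = 1L) {
  y <- mat$counts
  n <- nrow(y)
  stopifnot(nrow(neighbors$indices) == n)
  if (nrow(y) >= 10L && ncol(neighbors$indices) + 1L < 10L)
    warning("subgroups of ", ncol(neighbors$indices) + 1L,
            " regions are small; latent-factor estimation may be unstable")

  subgroups <- lapply(seq_len(n), function(i)
    sort(unique(c(i, neighbors$indices[i, ]))))
  keys <- vapply(subgroups, paste, "", collapse = ",")
  ukeys <- unique(keys)
  umembers <- subgroups[match(ukeys, keys)]

  fit_one <- function(members) {
    tryCatch({
      fit <- fit_poisson_latent(y[members, , drop = FALSE],
                                gc = annotations$gc[members],
                                lengths = annotations$length[members],
                                config = config)
      list(ok = TRUE, lambda = fit$lambda, K_used = fit$K_used,
           converged = fit$converged)
    }, error = function(e)
      list(ok = FALSE, message = conditionMessage(e)))
  }

  fits <- if (workers > 1L) {
    parallel::mclapply(umembers, fit_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(umembers, fit_one)
  }
  names(fits) <- ukeys

  lambda <- matrix(NA_real_, n, ncol(y), dimnames = dimnames(y))
  prov <- data.frame(region_id = mat$region_ids,
                     subgroup_size = lengths(subgroups),
                     K_used = NA_integer_, converged = NA,
                     failed = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fit <- fits[[keys[i]]]
    if (isTRUE(fit$ok)) {
      pos <- match(i, subgroups[[i]])
      lambda[i, ] <- fit$lambda[pos, ]
      prov$K_used[i] <- fit$K_used
      prov$converged[i] <- fit$converged
    } else {
      prov$failed[i] <- TRUE
    }
  }
  n_fail <- sum(prov$failed)
  if (n_fail > 0.10 * n)
    stop(n_fail, " of ", n, " subgroup normalizations failed (> 10%); first: ",
         fits[[keys[which(prov$failed)[1L]]]]$message)
  if (n_fail > 0) {
    warning(n_fail, " subgroup normalization(s) failed; rows flagged and ",
            "filled with the median-depth fallback")
    for (i in which(prov$failed))
      lambda[i, ] <- max(stats::median(y[i, ]), config$pseudocount)
  }
  new_normalized_matrix(lambda, prov)
}
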