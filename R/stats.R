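#' Sign-permutation test on per-subject effects
#'
#' Tests the group mean of participant-specific effects (e.g., accuracy
#' minus 50, correlation coefficients, shared-variance coefficients) against
#' zero by randomly multiplying each participant's value by +1 or -1. The
#' observed sample is included in the null distribution, so the smallest
#' attainable p is `1 / n_perm`.
#'
#' @param subject_values Numeric vector, one effect per subject (>= 2).
#' @param n_perm Number of permutations (the reference analysis uses 10,000).
#' @param tail `"right"` (default, effect > 0), `"left"`, or `"two"`.
#' @param seed Integer seed.
#' @return List with `p`, `observed` (mean effect), and `null` (permuted
#'   means, first entry = observed).
#' @export
sign_perm_test <- function(subject_values, n_perm = 10000, tail = "right",
                           seed = 1) {
  n <- length(subject_values)
  if (n < 2) stop("need >= 2 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  signs[1, ] <- 1                              # observed sample included
  null <- drop(signs %*% subject_values) / n
  obs <- mean(subject_values)
  eps <- 1e-12
  p <- switch(tail,
    right = mean(null >= obs - eps),
    left  = mean(null <= obs + eps),
    two   = mean(abs(null) >= abs(obs) - eps),
    stop("unknown tail: ", tail))
  list(p = p, observed = obs, null = null)
}

# Connected components of a logical array under orthogonal adjacency
# (2 neighbors in 1-D, 4 in 2-D, 6 in 3-D). Returns an integer label array.
label_clusters <- function(mask, dims) {
  mask <- array(mask, dims)
  nd <- length(dims)
  labels <- array(0L, dims)
  nxt <- 0L
  offsets <- diag(1, nd)
  idx_all <- which(mask)
  strides <- cumprod(c(1, dims[-nd]))
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      coord <- arrayInd(cur, dims)
      for (d in seq_len(nd)) for (s in c(-1L, 1L)) {
        nc <- coord
        nc[d] <- nc[d] + s
        if (nc[d] < 1 || nc[d] > dims[d]) next
        ni <- sum((nc - 1) * strides) + 1
        if (mask[ni] && labels[ni] == 0L) {
          labels[ni] <- nxt
          queue <- c(queue, ni)
        }
      }
    }
  }
  labels
}

#' Cluster-based permutation inference on 1-D/2-D/3-D effect maps
#'
#' Family-wise-error-controlled inference over contiguous grids (time
#' courses, time-time or time-frequency matrices, volumes). Per grid point,
#' sign-permutation p-values are computed; supra-threshold points
#' (`p < cdt`) are grouped into clusters under orthogonal adjacency and
#' scored by size; each observed cluster's p-value is its size's rank in the
#' permutation null distribution of the maximum cluster size.
#'
#' @param effect_maps subject x grid-point matrix (grid flattened
#'   column-major over `dims`).
#' @param dims Integer vector giving the grid shape (length 1, 2, or 3).
#' @param cdt Cluster definition threshold on the per-point permutation p
#'   (reference analysis: 0.005).
#' @param alpha Cluster-level significance threshold (reference: 0.05).
#' @param n_perm Number of sign permutations.
#' @param tail Tail for the per-point test (`"right"`, `"left"`, `"two"`).
#' @param seed Integer seed.
#' @return Object of class `stat_result`: `p_map` (per-point p, shaped
#'   `dims`), `cluster_id` (integer array), `cluster_p` (per cluster),
#'   `sig_mask` (logical array of points in clusters with `p <= alpha`),
#'   `max_null` (null max-cluster-size distribution).
#' @export
cluster_inference <- function(effect_maps, dims = ncol(effect_maps),
                              cdt = 0.005, alpha = 0.05, n_perm = 1000,
                              tail = "right", seed = 1) {
  effect_maps <- as.matrix(effect_maps)
  n_sub <- nrow(effect_maps); n_grid <- ncol(effect_maps)
  if (prod(dims) != n_grid) stop("prod(dims) must equal the grid size")
  if (n_sub < 2) stop("need >= 2 subjects")
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n_sub, replace = TRUE),
                  n_perm, n_sub)
  signs[1, ] <- 1
  perm_means <- signs %*% effect_maps / n_sub   # n_perm x grid
  # per-point permutation p for every permutation sample (row 1 = observed)
  p_of <- function(col) {
    r <- rank(col, ties.method = "min")
    switch(tail,
      right = (n_perm - r + 1) / n_perm,
      left  = rank(col, ties.method = "max") / n_perm,
      two   = {
        ra <- rank(abs(col), ties.method = "min")
        (n_perm - ra + 1) / n_perm
      },
      stop("unknown tail: ", tail))
  }
  p_all <- apply(perm_means, 2, p_of)           # n_perm x grid
  supra <- p_all < cdt
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (!any(supra[b, ])) { max_null[b] <- 0; next }
    lab <- label_clusters(supra[b, ], dims)
    max_null[b] <- max(tabulate(lab[lab > 0]))
  }
  obs_lab <- label_clusters(supra[1, ], dims)
  n_clust <- max(obs_lab)
  cluster_p <- if (n_clust > 0) {
    sizes <- tabulate(obs_lab[obs_lab > 0], nbins = n_clust)
    vapply(sizes, function(sz) mean(max_null >= sz), numeric(1))
  } else numeric(0)
  sig <- array(FALSE, dims)
  if (n_clust > 0) {
    for (cl in which(cluster_p <= alpha)) sig[obs_lab == cl] <- TRUE
  }
  structure(list(p_map = array(p_all[1, ], dims),
                 cluster_id = obs_lab,
                 cluster_p = cluster_p,
                 sig_mask = sig,
                 max_null = max_null),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("Cluster inference:", length(x$cluster_p), "cluster(s)")
  if (length(x$cluster_p))
    cat("; p =", paste(signif(x$cluster_p, 3), collapse = ", "))
  cat("\n  significant points:", sum(x$sig_mask), "/", length(x$sig_mask), "\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up false-discovery-rate control for small sets of unrelated
#' comparisons (e.g., per-layer RSA correlations).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param q FDR level (reference analysis: 0.05).
#' @return Logical rejection mask aligned with `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(logical(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' Bootstrap confidence interval for a group peak latency
#'
#' Resamples subjects with replacement, recomputes the group-mean curve,
#' takes its argmax (ties broken to the earliest index), and reports the
#' 2.5/97.5 percentiles of the resulting peak distribution.
#'
#' @param subject_curves subject x point matrix (e.g., decoding accuracy
#'   over time, correlation over layers).
#' @param n_boot Bootstrap samples (reference analysis: 1,000).
#' @param x Optional coordinate vector for the point axis (e.g., time in
#'   ms); defaults to indices.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `ci` (length 2), `peak` (observed group peak), and
#'   `boot_peaks`.
#' @export
bootstrap_peak_ci <- function(subject_curves, n_boot = 1000, x = NULL,
                              level = 0.95, seed = 1) {
  subject_curves <- as.matrix(subject_curves)
  n_sub <- nrow(subject_curves)
  if (n_sub < 2) stop("need >= 2 subjects")
  if (is.null(x)) x <- seq_len(ncol(subject_curves))
  mean_curve <- colMeans(subject_curves)
  if (diff(range(mean_curve)) == 0)
    warning("flat mean curve: peak is undefined, CI spans the full domain")
  set.seed(seed)
  boot_peaks <- replicate(n_boot, {
    bm <- colMeans(subject_curves[sample.int(n_sub, replace = TRUE), ,
                                  drop = FALSE])
    x[which.max(bm)]          # which.max ties -> earliest
  })
  a <- (1 - level) / 2
  list(ci = unname(stats::quantile(boot_peaks, c(a, 1 - a))),
       peak = x[which.max(mean_curve)],
       boot_peaks = boot_peaks)
}

#' Hedges' g for paired samples
#'
#' Standardized mean of the paired differences with the small-sample bias
#' correction `1 - 3 / (4 (n - 1) - 1)`.
#'
#' @param diffs Per-subject paired differences.
#' @return Hedges' g.
#' @export
hedges_g <- function(diffs) {
  n <- length(diffs)
  s <- stats::sd(diffs)
  if (s == 0) return(if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf)
  (mean(diffs) / s) * (1 - 3 / (4 * (n - 1) - 1))
}

#' Paired peak-shift permutation test with effect size
#'
#' Tests whether a per-subject quantity (e.g., the peak model layer of an
#' RSA profile) differs between two conditions by randomly reassigning the
#' condition labels within each participant (equivalently, flipping the sign
#' of each paired difference) and recomputing the mean difference. Reports
#' the two-tailed p-value and Hedges' g.
#'
#' @param cond_a,cond_b Per-subject values under each condition (paired).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `p` (two-tailed), `g` (Hedges' g), `observed` (mean
#'   difference), `null`.
#' @export
peak_shift_test <- function(cond_a, cond_b, n_perm = 10000, seed = 1) {
  if (length(cond_a) != length(cond_b)) stop("conditions must be paired")
  n <- length(cond_a)
  if (n < 3) stop("need >= 3 subjects")
  d <- cond_a - cond_b
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  signs[1, ] <- 1
  null <- drop(signs %*% d) / n
  obs <- mean(d)
  eps <- 1e-12
  p <- mean(abs(null) >= abs(obs) - eps)
  list(p = p, g = hedges_g(d), observed = obs, null = null)
}
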