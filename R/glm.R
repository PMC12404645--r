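#' Parametric haemodynamic response function family
#'
#' A graded family of double-gamma HRFs with peak latencies from
#' `peak_min_s` to `peak_max_s` in `n_kernels` steps (dispersion scales with
#' latency), peak-normalized to 1. Used for voxel-specific HRF selection:
#' the GLM is fit once per family member and each voxel keeps the member
#' with the lowest average residual.
#'
#' @param n_kernels Number of kernels (default 20).
#' @param peak_min_s,peak_max_s Peak latency range in seconds.
#' @param dt_s Sampling step of the kernels in seconds.
#' @param duration_s Kernel support in seconds.
#' @param undershoot_scale Relative amplitude of the undershoot gamma.
#' @return Object of class `hrf_family`: `kernels` (list of sampled
#'   responses), `peak_s` (latencies, strictly increasing), `dt_s`.
#' @examples
#' fam <- hrf_family()
#' fam$peak_s[c(1, 20)]
#' @export
hrf_family <- function(n_kernels = 20, peak_min_s = 3, peak_max_s = 9,
                       dt_s = 0.1, duration_s = 32, undershoot_scale = 0.35) {
  peaks <- seq(peak_min_s, peak_max_s, length.out = n_kernels)
  t_s <- seq(0, duration_s, by = dt_s)
  kernels <- lapply(peaks, function(p) {
    shape1 <- p + 1                     # gamma with rate 1 peaks at shape - 1
    shape2 <- p + 11
    h <- stats::dgamma(t_s, shape = shape1, rate = 1) -
      undershoot_scale * stats::dgamma(t_s, shape = shape2, rate = 1)
    h / max(h)
  })
  structure(list(kernels = kernels, peak_s = peaks, dt_s = dt_s,
                 n_kernels = as.integer(n_kernels)),
            class = "hrf_family")
}

#' @export
print.hrf_family <- function(x, ...) {
  cat("HRFFamily:", x$n_kernels, "double-gamma kernels, peak",
      min(x$peak_s), "-", max(x$peak_s), "s\n")
  invisible(x)
}

# Condition regressors for one HRF: event trains on a fine grid convolved
# with the kernel and sampled at scan times.
design_matrix <- function(events, family, kernel_index, tr, n_scans) {
  dt <- family$dt_s
  h <- family$kernels[[kernel_index]]
  dur <- n_scans * tr
  n_fine <- ceiling(dur / dt) + length(h)
  conds <- sort(unique(events$condition))
  X <- matrix(0, n_scans, length(conds))
  scan_idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1
  for (ci in seq_along(conds)) {
    train <- numeric(n_fine)
    ev <- events[events$condition == conds[ci], , drop = FALSE]
    for (e in seq_len(nrow(ev))) {
      on <- round(ev$onset[e] / dt) + 1
      off <- on + max(1, round(ev$duration[e] / dt)) - 1
      train[on:off] <- 1
    }
    reg <- stats::convolve(train, rev(h), type = "open")[seq_len(n_fine)] * dt
    X[, ci] <- reg[scan_idx]
  }
  colnames(X) <- paste0("cond", conds)
  X
}

#' Fit condition GLMs with per-voxel HRF selection
#'
#' Evaluates one GLM per member of the HRF family — condition regressors
#' convolved with that member's response, plus shared nuisance regressors
#' and an intercept — and, for each voxel, keeps the member with the lowest
#' mean squared residual over the whole series (ties broken toward the
#' lowest index). Betas from the selected member's GLM are returned.
#'
#' @param series scan x voxel matrix of BOLD time series.
#' @param events data.frame with `onset`, `duration` (seconds), `condition`
#'   (BIDS-style events table).
#' @param family An [hrf_family()].
#' @param nuisance Optional scan x p matrix of nuisance regressors shared
#'   across candidate GLMs.
#' @param tr Repetition time in seconds.
#' @return Object of class `glm_fit`: `betas` (condition x voxel, from the
#'   selected HRF per voxel), `hrf_index` (per voxel), `mse` (family x voxel
#'   mean squared residuals), `conditions`.
#' @export
fit_glm_hrf_select <- function(series, events, family = hrf_family(),
                               nuisance = NULL, tr = 2) {
  series <- as.matrix(series)
  n_scans <- nrow(series); n_vox <- ncol(series)
  if (max(events$onset) >= n_scans * tr)
    stop("events extend beyond the series duration")
  conds <- sort(unique(events$condition))
  n_cond <- length(conds)
  mse <- matrix(0, family$n_kernels, n_vox)
  betas_all <- vector("list", family$n_kernels)
  for (k in seq_len(family$n_kernels)) {
    Xc <- design_matrix(events, family, k, tr, n_scans)
    X <- cbind(Xc, nuisance, intercept = 1)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrx$pivot[seq_len(qrx$rank)])]
      stop("rank-deficient design for HRF ", k, "; collinear regressors: ",
           paste(bad, collapse = ", "))
    }
    coefs <- qr.coef(qrx, series)
    resid <- series - X %*% coefs
    mse[k, ] <- colMeans(resid^2)
    betas_all[[k]] <- coefs[seq_len(n_cond), , drop = FALSE]
  }
  hrf_index <- apply(mse, 2, which.min)   # which.min ties -> lowest index
  betas <- matrix(0, n_cond, n_vox,
                  dimnames = list(paste0("cond", conds), NULL))
  for (v in seq_len(n_vox)) betas[, v] <- betas_all[[hrf_index[v]]][, v]
  structure(list(betas = betas, hrf_index = hrf_index, mse = mse,
                 conditions = conds),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit:", length(x$conditions), "conditions x", ncol(x$betas),
      "voxels; HRF indices", paste(range(x$hrf_index), collapse = "-"), "\n")
  invisible(x)
}
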