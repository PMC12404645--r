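#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over a baseline window from the
#' entire epoch (the conventional pre-stimulus baseline correction).
#'
#' @param epochs An [epoch_set()].
#' @param window Numeric length-2 interval in ms, `[from, to)`; defaults to
#'   the 200 ms before stimulus onset.
#' @return A baseline-corrected `epoch_set`.
#' @examples
#' d <- design_spec(n_objects = 2, trials_per_cell = 4, n_channels = 4)
#' e <- simulate_eeg_dataset(d, ground_truth(d), seed = 1)[[1]]
#' b <- baseline_correct(e)
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(base)  # recycles over the time axis
  out
}

# Ledoit-Wolf analytic shrinkage of a covariance toward the scaled identity,
# from centered observation rows.
shrink_covariance <- function(resid) {
  n <- nrow(resid); p <- ncol(resid)
  s <- crossprod(resid) / n
  m <- sum(diag(s)) / p
  d2 <- sum((s - diag(m, p))^2) / p
  x2 <- resid^2
  b2 <- sum(crossprod(x2) / n - s^2) / (n * p)
  b2 <- min(b2, d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  list(sigma = (1 - lambda) * s + diag(lambda * m, p), lambda = lambda)
}

#' Multivariate noise normalization (whitening) of epoch data
#'
#' Estimates the error (within-condition residual) channel covariance —
#' residuals around each object x mask cell's mean time course, pooled over
#' conditions and time points — applies analytic (Ledoit-Wolf) shrinkage
#' toward the scaled identity, and multiplies the data by the inverse matrix
#' square root. After whitening, the pooled residual covariance is
#' approximately the identity, which improves the SNR and reliability of
#' downstream pattern analyses.
#'
#' One whitening matrix is computed per call on all trials supplied (both
#' masking conditions pooled), so within- and cross-condition comparisons
#' share a single transform.
#'
#' @param epochs An [epoch_set()] with at least 2 trials in every object x
#'   mask cell.
#' @return A whitened `epoch_set`; the whitening matrix is attached as
#'   attribute `"whitening"` and the shrinkage intensity as `"shrinkage"`.
#' @export
mnn_whiten <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  cell <- interaction(epochs$object_label, epochs$mask_label, drop = TRUE)
  if (any(table(cell) < 2)) stop("every object x mask cell needs >= 2 trials")
  d <- dim(epochs$data)
  n_trial <- d[1]; n_chan <- d[2]; n_time <- d[3]
  resid <- matrix(0, n_trial * n_time, n_chan)
  for (g in levels(cell)) {
    idx <- which(cell == g)
    cell_mean <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    for (i in idx) {
      r <- epochs$data[i, , ] - cell_mean        # chan x time
      rows <- ((i - 1) * n_time + 1):(i * n_time)
      resid[rows, ] <- t(r)
    }
  }
  sh <- shrink_covariance(resid)
  eg <- eigen(sh$sigma, symmetric = TRUE)
  w <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-12))) %*% t(eg$vectors)
  out <- epochs
  for (t in seq_len(n_time)) out$data[, , t] <- epochs$data[, , t] %*% w
  attr(out, "whitening") <- w
  attr(out, "shrinkage") <- sh$lambda
  out
}
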