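#' Complex Morlet wavelet bank
#'
#' Builds Gaussian-enveloped complex exponentials covering `f_min`..`f_max`
#' in `n` logarithmically spaced frequencies. The Gaussian taper varies with
#' frequency: the temporal full-width-half-maximum (FWHM) is scheduled
#' log-linearly from `fwhm_max_ms` at the lowest frequency down to
#' `fwhm_min_ms` at the highest. By Fourier uncertainty the corresponding
#' spectral FWHM — measured on the power spectrum — grows as frequency
#' increases: `FWHM_f = 4 log(2) / (pi * FWHM_t * sqrt(2))`, about 1 Hz at
#' the 4-Hz end and 31 Hz at the 100-Hz end under the defaults.
#'
#' Each kernel's envelope is normalized to unit integral, and each kernel is
#' sampled on its own symmetric grid extending 3.5 Gaussian SDs either side
#' of zero.
#'
#' @param f_min,f_max Frequency range in Hz.
#' @param n Number of frequencies (>= 2).
#' @param fwhm_max_ms,fwhm_min_ms Temporal FWHM at `f_min` / `f_max`.
#' @param srate_hz Sampling rate of the kernels (and of the data they will be
#'   applied to); the default 500 Hz gives the 2-ms analysis step.
#' @return An object of class `wavelet_bank`: `freqs_hz`, `temporal_fwhm_ms`
#'   (scheduled), `kernels` (list of complex vectors), `kernel_time_ms`,
#'   `srate_hz`.
#' @examples
#' bank <- build_wavelet_bank()
#' measure_envelope_fwhm(bank$kernels[[1]], bank$srate_hz)  # ~500 ms
#' @export
build_wavelet_bank <- function(f_min = 4, f_max = 100, n = 50,
                               fwhm_max_ms = 500, fwhm_min_ms = 20,
                               srate_hz = 500) {
  if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max")
  if (n < 2) stop("n must be >= 2")
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n))
  fwhm <- exp(seq(log(fwhm_max_ms), log(fwhm_min_ms), length.out = n))
  if (any(fwhm < 1000 / freqs))
    warning("temporal FWHM shorter than one oscillation cycle for some frequencies")
  dt <- 1000 / srate_hz
  kernels <- vector("list", n)
  times <- vector("list", n)
  for (i in seq_len(n)) {
    sigma <- fwhm[i] / (2 * sqrt(2 * log(2)))           # ms
    half <- ceiling(3.5 * sigma / dt) * dt
    t_ms <- seq(-half, half, by = dt)
    env <- exp(-t_ms^2 / (2 * sigma^2))
    env <- env / sum(env * dt / 1000)                    # unit-integral envelope
    kernels[[i]] <- env * exp(2i * pi * freqs[i] * t_ms / 1000)
    times[[i]] <- t_ms
  }
  structure(list(freqs_hz = freqs, temporal_fwhm_ms = fwhm,
                 kernels = kernels, kernel_time_ms = times,
                 srate_hz = srate_hz),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat("WaveletBank:", length(x$freqs_hz), "frequencies,",
      round(min(x$freqs_hz), 2), "-", round(max(x$freqs_hz), 2), "Hz @",
      x$srate_hz, "Hz sampling\n")
  cat("  temporal FWHM:", round(max(x$temporal_fwhm_ms)), "->",
      round(min(x$temporal_fwhm_ms)), "ms\n")
  invisible(x)
}

# Whole-signal reflection padding (period 2(n-1)), valid for pads of any
# length relative to the signal.
reflect_pad <- function(x, n_pad) {
  n <- length(x)
  if (n == 1) return(rep(x, n + 2 * n_pad))
  k <- (1 - n_pad):(n + n_pad)
  m <- (k - 1) %% (2 * n - 2)
  idx <- ifelse(m < n, m + 1, 2 * n - 1 - m)
  x[idx]
}

# Interpolated full width at half maximum of a sampled curve y over axis x.
fwhm_of_curve <- function(x, y) {
  half <- max(y) / 2
  above <- which(y >= half)
  if (!length(above)) return(NA_real_)
  lo <- above[1]; hi <- above[length(above)]
  left <- if (lo == 1) x[1] else {
    x[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) * (x[lo] - x[lo - 1])
  }
  right <- if (hi == length(y)) x[length(y)] else {
    x[hi] + (y[hi] - half) / (y[hi] - y[hi + 1]) * (x[hi + 1] - x[hi])
  }
  right - left
}

#' Measure the temporal-envelope FWHM of a wavelet kernel
#' @param kernel Complex kernel vector.
#' @param srate_hz Sampling rate the kernel was built at.
#' @return FWHM of the envelope (modulus) in ms.
#' @export
measure_envelope_fwhm <- function(kernel, srate_hz) {
  n <- length(kernel)
  t_ms <- (seq_len(n) - (n + 1) / 2) * 1000 / srate_hz
  fwhm_of_curve(t_ms, Mod(kernel))
}

#' Measure the spectral FWHM of a wavelet kernel on its power spectrum
#' @param kernel Complex kernel vector.
#' @param srate_hz Sampling rate the kernel was built at.
#' @param n_fft Zero-padded FFT length for fine frequency resolution.
#' @return FWHM of the spectral power peak in Hz.
#' @export
measure_spectral_fwhm <- function(kernel, srate_hz, n_fft = 2^17) {
  padded <- c(kernel, rep(0 + 0i, n_fft - length(kernel)))
  pw <- Mod(stats::fft(padded))^2
  freqs <- (seq_len(n_fft) - 1) * srate_hz / n_fft
  keep <- freqs <= srate_hz / 2
  fwhm_of_curve(freqs[keep], pw[keep])
}

#' Time-frequency decomposition of an epoch set
#'
#' Convolves every trial and channel with each complex Morlet kernel in the
#' bank, then downsamples the output time axis. Power is the magnitude of
#' the complex coefficient; phase is carried as the unit-normalized
#' (cosine, sine) pair, extracted with [tfr_phase()].
#'
#' The epoch must be sampled at the bank's rate and be at least as long as
#' the widest kernel; shorter epochs raise an edge-effect error unless
#' `pad = TRUE` requests reflection padding. The recommended workflow is to
#' generate epochs on a long fine grid (e.g., -600..1200 ms at 2 ms), then
#' crop after the transform via `crop_ms`.
#'
#' @param epochs An [epoch_set()].
#' @param bank A [build_wavelet_bank()].
#' @param downsample_ms Output time step in ms (samples whose timestamp is a
#'   multiple of this are kept).
#' @param crop_ms Optional `c(from, to)` interval to crop the output axis to.
#' @param pad Reflect-pad short epochs instead of erroring.
#' @return An object of class `tfr_set`: complex `coeffs`
#'   (trial x channel x frequency x time), `freqs_hz`, `time_ms`, and the
#'   epoch labels.
#' @export
tfr_transform <- function(epochs, bank, downsample_ms = 20, crop_ms = NULL,
                          pad = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "wavelet_bank"))
  dt <- 1000 / bank$srate_hz
  if (max(abs(diff(epochs$time_ms) - dt)) > 1e-6)
    stop("epoch sampling (", diff(epochs$time_ms)[1],
         " ms) does not match the bank's ", dt, " ms step")
  d <- dim(epochs$data)
  n_trial <- d[1]; n_chan <- d[2]; n_time <- d[3]
  lens <- lengths(bank$kernels)
  max_len <- max(lens)
  n_pad <- 0L
  if (n_time < max_len) {
    if (!pad)
      stop("epoch (", n_time, " samples) shorter than the widest kernel (",
           max_len, " samples); generate longer epochs or set pad = TRUE")
    n_pad <- max_len - n_time
  }
  nfft <- stats::nextn(n_time + 2 * n_pad + max_len - 1, 2)
  kern_fft <- lapply(bank$kernels, function(k)
    stats::fft(c(k, rep(0 + 0i, nfft - length(k)))))
  n_freq <- length(bank$kernels)
  keep_t <- which(abs(epochs$time_ms / downsample_ms -
                        round(epochs$time_ms / downsample_ms)) < 1e-6)
  out_time <- epochs$time_ms[keep_t]
  if (!is.null(crop_ms)) {
    sel <- out_time >= crop_ms[1] & out_time <= crop_ms[2]
    keep_t <- keep_t[sel]; out_time <- out_time[sel]
  }
  coeffs <- array(0 + 0i, c(n_trial, n_chan, n_freq, length(keep_t)))
  for (tr in seq_len(n_trial)) for (ch in seq_len(n_chan)) {
    x <- epochs$data[tr, ch, ]
    if (n_pad > 0) x <- reflect_pad(x, n_pad)
    x_fft <- stats::fft(c(x, rep(0, nfft - length(x))))
    for (f in seq_len(n_freq)) {
      conv <- stats::fft(x_fft * kern_fft[[f]], inverse = TRUE) / nfft
      center <- (lens[f] + 1) / 2
      aligned <- conv[(center + n_pad) + seq_len(n_time) - 1] * dt / 1000
      coeffs[tr, ch, f, ] <- aligned[keep_t]
    }
  }
  structure(list(coeffs = coeffs, freqs_hz = bank$freqs_hz, time_ms = out_time,
                 object_label = epochs$object_label,
                 mask_label = epochs$mask_label,
                 channel_ids = epochs$channel_ids),
            class = "tfr_set")
}

#' @export
print.tfr_set <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("TFRSet:", d[1], "trials x", d[2], "channels x", d[3], "frequencies x",
      d[4], "time points\n")
  invisible(x)
}

#' Power view of a TFR set
#' @param tfr A `tfr_set`.
#' @return Non-negative array (trial x channel x frequency x time) of
#'   coefficient magnitudes.
#' @export
tfr_power <- function(tfr) Mod(tfr$coeffs)

#' Phase view of a TFR set
#'
#' Phase is represented as the unit-normalized (cosine, sine) pair of each
#' complex coefficient, concatenated along the channel axis: with 64 channels
#' the phase feature dimension is 128. Where power is (numerically) zero the
#' phase is undefined and returned as `NaN`.
#'
#' @param tfr A `tfr_set`.
#' @param eps Magnitude below which phase is treated as undefined.
#' @return Array trial x (2 * channel) x frequency x time; the first
#'   `n_channels` rows of the feature axis are cosines, the rest sines.
#' @export
tfr_phase <- function(tfr, eps = 1e-12) {
  m <- Mod(tfr$coeffs)
  u <- tfr$coeffs / m
  u[m < eps] <- complex(real = NaN, imaginary = NaN)
  d <- dim(tfr$coeffs)
  out <- array(NA_real_, c(d[1], 2 * d[2], d[3], d[4]))
  out[, seq_len(d[2]), , ] <- Re(u)
  out[, d[2] + seq_len(d[2]), , ] <- Im(u)
  out
}
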