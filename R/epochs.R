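#' Labeled EEG epoch container
#'
#' Holds a trial x channel x time array together with per-trial object and
#' mask labels, the time axis in ms, and channel identifiers. This is the
#' substrate for baseline correction, noise normalization, wavelet
#' decomposition, and decoding.
#'
#' @param data Numeric array, trial x channel x time.
#' @param object_label Integer vector (1..K), one entry per trial.
#' @param mask_label Character/factor vector, one entry per trial.
#' @param time_ms Numeric vector of per-sample timestamps, strictly increasing.
#' @param channel_ids Optional channel names; defaults to `ch01..chNN`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, object_label, mask_label, time_ms,
                      channel_ids = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a trial x channel x time array")
  n_trial <- dim(data)[1]; n_chan <- dim(data)[2]; n_time <- dim(data)[3]
  if (length(object_label) != n_trial) stop("object_label does not align with the trial axis")
  if (length(mask_label) != n_trial) stop("mask_label does not align with the trial axis")
  if (length(time_ms) != n_time) stop("time_ms does not align with the time axis")
  if (any(diff(time_ms) <= 0)) stop("time_ms must be strictly increasing")
  if (anyNA(data)) stop("epoch data must not contain missing samples")
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(n_chan))
  if (length(channel_ids) != n_chan) stop("channel_ids does not align with the channel axis")
  structure(list(
    data = data,
    object_label = as.integer(object_label),
    mask_label = as.character(mask_label),
    time_ms = as.numeric(time_ms),
    channel_ids = as.character(channel_ids)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3], "samples\n")
  cat("  time:", min(x$time_ms), "..", max(x$time_ms), "ms\n")
  cat("  objects:", length(unique(x$object_label)),
      "| mask conditions:", paste(unique(x$mask_label), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an epoch set by trial
#' @param epochs An `epoch_set`.
#' @param idx Trial indices or logical mask.
#' @return A new `epoch_set` containing the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE],
            epochs$object_label[idx], epochs$mask_label[idx],
            epochs$time_ms, epochs$channel_ids)
}
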