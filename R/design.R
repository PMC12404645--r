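#' Experimental design specification
#'
#' Describes the factorial layout of a backward-masking experiment: a set of
#' object conditions crossed with two masking conditions (an early mask that
#' curtails recurrent processing and a late mask that spares it), with a fixed
#' number of EEG trials per cell, a channel montage, an epoch time grid, and
#' the fMRI run structure.
#'
#' Defaults reproduce the reference design: 24 objects x 2 masking conditions
#' x 53 trials (2,544 EEG trials per subject), 64 channels, epochs from -200
#' to 800 ms in 10-ms steps, and 12 fMRI runs with 2 presentations of each
#' condition per run.
#'
#' @param n_objects Number of object conditions (>= 2).
#' @param mask_conditions Ordered labels of the masking conditions.
#' @param trials_per_cell EEG trials per object x mask cell (>= 4, so that
#'   four pseudo-trial bins are always supported).
#' @param n_channels Number of EEG channels.
#' @param time_start,time_stop,time_step Epoch time grid in ms.
#' @param n_runs Number of fMRI runs.
#' @param presentations_per_run Presentations of each object x mask condition
#'   per fMRI run.
#' @param n_subjects Number of subjects to simulate.
#' @return An object of class `design_spec`.
#' @examples
#' d <- design_spec(n_objects = 8, trials_per_cell = 12, n_subjects = 3)
#' d
#' @export
design_spec <- function(n_objects = 24,
                        mask_conditions = c("early", "late"),
                        trials_per_cell = 53,
                        n_channels = 64,
                        time_start = -200, time_stop = 800, time_step = 10,
                        n_runs = 12,
                        presentations_per_run = 2,
                        n_subjects = 10) {
  if (n_objects < 2) stop("n_objects must be >= 2")
  if (trials_per_cell < 4) stop("trials_per_cell must be >= 4 (four pseudo-trial bins)")
  if (time_step <= 0 || time_stop <= time_start) stop("time grid must be strictly increasing")
  if (length(mask_conditions) < 1) stop("at least one mask condition required")
  time_ms <- seq(time_start, time_stop, by = time_step)
  structure(list(
    n_objects = as.integer(n_objects),
    mask_conditions = as.character(mask_conditions),
    trials_per_cell = as.integer(trials_per_cell),
    n_channels = as.integer(n_channels),
    time_ms = time_ms,
    n_runs = as.integer(n_runs),
    presentations_per_run = as.integer(presentations_per_run),
    n_subjects = as.integer(n_subjects)
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", x$n_objects, "objects x", length(x$mask_conditions),
      "mask conditions x", x$trials_per_cell, "trials/cell\n")
  cat("  EEG:", x$n_channels, "channels, epochs",
      min(x$time_ms), "..", max(x$time_ms), "ms (",
      length(x$time_ms), "samples )\n")
  cat("  fMRI:", x$n_runs, "runs x", x$presentations_per_run,
      "presentations/condition/run\n")
  cat("  Subjects:", x$n_subjects, "\n")
  invisible(x)
}

#' Total EEG trials per subject implied by a design
#' @param design A `design_spec`.
#' @return Integer trial count (objects x mask conditions x trials per cell).
#' @export
n_trials_per_subject <- function(design) {
  design$n_objects * length(design$mask_conditions) * design$trials_per_cell
}

#' Condition betas per fMRI run implied by a design
#' @param design A `design_spec`.
#' @return Integer count (objects x mask conditions x presentations per run).
#' @export
n_betas_per_run <- function(design) {
  design$n_objects * length(design$mask_conditions) * design$presentations_per_run
}
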