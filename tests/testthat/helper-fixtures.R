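# Small designs and ground truths shared across tests. Everything is built
# in code at test time; sizes are kept small so the decoding-heavy tests
# stay fast.

tiny_design <- function(n_objects = 4, trials_per_cell = 8, n_channels = 16,
                        time_start = 0, time_stop = 200, time_step = 50,
                        n_subjects = 1, ...) {
  design_spec(n_objects = n_objects, trials_per_cell = trials_per_cell,
              n_channels = n_channels, time_start = time_start,
              time_stop = time_stop, time_step = time_step,
              n_subjects = n_subjects, ...)
}

# Ground truth with independently settable component amplitudes.
truth_with <- function(design, ff = 1, rec = 0.8, osc = 0.5,
                       rec_by_mask = c(early = 0.2, late = 1),
                       noise_scale = 1, overlap = 1, seed = 1, ...) {
  ground_truth(design,
               feedforward = list(peak_ms = 120, fwhm_ms = 80, amplitude = ff),
               recurrent = list(onset_ms = 150, plateau_ms = 450,
                                amplitude = rec,
                                amplitude_by_mask = rec_by_mask),
               oscillatory = list(freq_hz = 10, amplitude = osc,
                                  onset_ms = 50),
               noise = list(rho = 0.3, scale = noise_scale),
               pattern_overlap = overlap, seed = seed, ...)
}

null_truth <- function(design, seed = 1) {
  truth_with(design, ff = 0, rec = 0, osc = 0,
             rec_by_mask = c(early = 0, late = 0), seed = seed)
}

# Run-wise beta array (run x condition x voxel) with fixed class patterns.
toy_betas <- function(n_runs = 12, k = 4, n_vox = 10, noise = 0, seed = 1) {
  set.seed(seed)
  pats <- matrix(rnorm(k * n_vox), k, n_vox)
  b <- array(0, c(n_runs, k, n_vox))
  for (r in seq_len(n_runs)) {
    b[r, , ] <- pats + matrix(rnorm(k * n_vox, sd = noise), k, n_vox)
  }
  b
}
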