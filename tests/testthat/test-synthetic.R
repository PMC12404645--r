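test_that("design counts match the reference layout", {
  d <- design_spec()
  expect_equal(n_trials_per_subject(d), 24 * 2 * 53)
  expect_equal(n_betas_per_run(d), 24 * 2 * 2)
  expect_error(design_spec(n_objects = 1), "n_objects")
  expect_error(design_spec(trials_per_cell = 3), "pseudo-trial")
  expect_error(design_spec(time_start = 0, time_stop = -10), "increasing")
})

test_that("model RDM sets shift geometry smoothly across layers", {
  m <- make_model_rdms(8, n_objects = 12, seed = 7)
  expect_length(m$rdms, 8)
  r12 <- rdm_correlate(m$rdms[[1]], m$rdms[[2]])
  r18 <- rdm_correlate(m$rdms[[1]], m$rdms[[8]])
  expect_gt(r12, r18)
  # endpoints equal the two bases for n_layers = 2
  m2 <- make_model_rdms(2, n_objects = 12, seed = 7)
  expect_equal(unclass(m2$rdms[[1]]),
               unclass(rdm_from_features(m2$features[[1]])))
  expect_error(make_model_rdms(1), "n_layers")
  # determinism
  expect_identical(make_model_rdms(4, n_objects = 6, seed = 3),
                   make_model_rdms(4, n_objects = 6, seed = 3))
})

test_that("EEG simulation honours the design and is seed-deterministic", {
  d <- tiny_design(n_objects = 3, trials_per_cell = 5, n_channels = 6,
                   n_subjects = 2)
  gt <- truth_with(d)
  eeg <- simulate_eeg_dataset(d, gt, seed = 11)
  expect_length(eeg, 2)
  expect_equal(dim(eeg[[1]]$data)[1], 3 * 2 * 5)
  expect_equal(as.vector(table(eeg[[1]]$object_label)), rep(10, 3))
  expect_equal(as.vector(table(eeg[[1]]$mask_label)), rep(15, 2))
  expect_identical(eeg, simulate_eeg_dataset(d, gt, seed = 11))
  d_bad <- tiny_design(n_channels = 99)
  expect_error(simulate_eeg_dataset(d_bad, gt, seed = 1), "match")
})

test_that("mask-dependent recurrent amplitude separates the conditions", {
  # noiseless: the late-mask signal carries the sustained component, the
  # early-mask signal mostly does not
  d <- tiny_design(n_objects = 2, trials_per_cell = 4, n_channels = 8,
                   time_start = -100, time_stop = 600, time_step = 20)
  gt <- truth_with(d, ff = 0, rec = 1, osc = 0, noise_scale = 0)
  e <- simulate_eeg_dataset(d, gt, seed = 1)[[1]]
  late_power <- mean(e$data[e$mask_label == "late", , e$time_ms > 250]^2)
  early_power <- mean(e$data[e$mask_label == "early", , e$time_ms > 250]^2)
  expect_gt(late_power, 10 * early_power)
})

test_that("fMRI betas carry the planted ROI-layer geometry", {
  d <- tiny_design(n_objects = 6, n_runs = 4, n_subjects = 1)
  gt <- truth_with(d)
  m <- make_model_rdms(8, n_objects = 6, seed = 2)
  fm <- simulate_fmri_dataset(d, gt, m, seed = 3, noise_scale = 0,
                              volume_dim = c(5, 5, 5),
                              signal_cube = c(1, 1, 1, 2))
  expect_equal(dim(fm[[1]]$rois$EVC)[2], n_betas_per_run(d))
  # zero noise: run-wise patterns identical
  expect_equal(fm[[1]]$rois$EVC[1, , ], fm[[1]]$rois$EVC[2, , ])
  # noiseless RDM peaks at the max-weight layer
  peak_layer <- function(roi, mask) {
    b <- average_presentations(fm[[1]]$rois[[roi]], mask = mask)
    r <- sapply(m$rdms, function(x)
      rdm_correlate(rdm_from_features(b[1, , ]), x))
    which.max(r)
  }
  expect_equal(peak_layer("EVC", "early"), 2)
  expect_equal(peak_layer("LOC", "late"), 8)
  gt_bad <- gt; gt_bad$roi_geometry <- list()
  expect_error(simulate_fmri_dataset(d, gt_bad, m, seed = 1), "roi_geometry")
})

test_that("zero-amplitude truth produces chance-level decodable data", {
  d <- tiny_design(n_objects = 3, trials_per_cell = 8, n_channels = 8,
                   time_start = 0, time_stop = 100, time_step = 50)
  eeg <- simulate_eeg_dataset(d, null_truth(d), seed = 5)
  tc <- decode_timecourse(eeg[[1]], "within-late", n_reps = 4, seed = 6)
  expect_lt(abs(mean(tc$timecourse) - 50), 6)
})

test_that("decoding accuracy grows with signal amplitude", {
  d <- tiny_design(n_objects = 3, trials_per_cell = 8, n_channels = 12,
                   time_start = 50, time_stop = 150, time_step = 50)
  accs <- sapply(c(0, 0.6, 2), function(a) {
    gt <- truth_with(d, ff = a, rec = 0, osc = 0, noise_scale = 1, seed = 2)
    eeg <- simulate_eeg_dataset(d, gt, seed = 7)
    mean(decode_timecourse(eeg[[1]], "within-late", n_reps = 3,
                           seed = 8)$timecourse)
  })
  expect_true(all(diff(accs) > -2))   # monotone up to Monte-Carlo error
  expect_gt(accs[3], accs[1] + 10)
})

test_that("simulated voxel time series follow their assigned HRF", {
  fam <- hrf_family()
  sim <- simulate_fmri_timeseries(c(5, 12), fam, noise_sd = 0, seed = 3)
  expect_equal(ncol(sim$series), 2)
  # noiseless: refitting with the generating kernel leaves zero residual
  fit <- fit_glm_hrf_select(sim$series, sim$events, fam)
  expect_equal(fit$hrf_index, c(5, 12))
  expect_lt(fit$mse[5, 1], 1e-20)
  expect_error(simulate_fmri_timeseries(c(0), fam), "out of range")
})
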