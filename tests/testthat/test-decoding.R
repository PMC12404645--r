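test_that("pseudo-trial binning drops the surplus and averages the rest", {
  set.seed(1)
  x <- matrix(rnorm(53 * 4), 53, 4)
  p <- bin_pseudotrials(x, 4)
  asg <- attr(p, "assignment")
  expect_equal(as.vector(table(asg[asg > 0])), rep(13, 4))
  expect_equal(sum(asg == 0), 1)
  expect_equal(p[2, ], colMeans(x[asg == 2, , drop = FALSE]))
  # 4 trials, 4 bins: pseudo-trials are the trials (up to order)
  p4 <- bin_pseudotrials(x[1:4, ], 4)
  expect_equal(p4[order(attr(p4, "assignment")), ], x[1:4, ])
  # fixed seed reproduces the binning
  set.seed(99); a1 <- attr(bin_pseudotrials(x, 4), "assignment")
  set.seed(99); a2 <- attr(bin_pseudotrials(x, 4), "assignment")
  expect_identical(a1, a2)
  expect_error(bin_pseudotrials(x[1:3, ], 4), "fewer trials")
})

test_that("pairwise accuracy is 100% on separated classes, ~50% on nulls", {
  set.seed(2)
  a <- matrix(rnorm(4 * 6), 4, 6) + 5
  b <- matrix(rnorm(4 * 6), 4, 6) - 5
  expect_equal(pairwise_accuracy(a, b), 100)
  # shuffled labels on separable data average to chance
  accs <- replicate(200, {
    pool <- rbind(a, b)[sample(8), ]
    pairwise_accuracy(pool[1:4, ], pool[5:8, ])
  })
  expect_lt(abs(mean(accs) - 50), 6)
  expect_error(pairwise_accuracy(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "more than one")
  expect_error(pairwise_accuracy(a, b[1:3, ]), "equal")
})

test_that("accuracy matrices validate and aggregate correctly", {
  m <- matrix(c(NA, 60, 70, 80,
                60, NA, 55, 65,
                70, 55, NA, 75,
                80, 65, 75, NA), 4, 4)
  am <- accuracy_matrix(m)
  expect_equal(grand_average(am), mean(c(60, 70, 80, 55, 65, 75)))
  # between-category mask for categories {1,2} vs {3,4}: hand-computed
  between <- outer(1:4, 1:4, function(i, j) (i <= 2) != (j <= 2))
  expect_equal(aggregate_pairs(am, between), mean(c(70, 80, 55, 65)))
  single <- matrix(FALSE, 4, 4); single[1, 2] <- single[2, 1] <- TRUE
  expect_equal(aggregate_pairs(am, single), 60)
  all_off <- matrix(TRUE, 4, 4)
  expect_equal(aggregate_pairs(am, all_off), grand_average(am))
  expect_error(aggregate_pairs(am, matrix(FALSE, 4, 4)), "no off-diagonal")
  expect_error(accuracy_matrix(matrix(200, 2, 2)), "\\[0, 100\\]")
})

test_that("time-resolved decoding recovers strong signal and stays symmetric", {
  d <- tiny_design(n_objects = 3, trials_per_cell = 8, n_channels = 12,
                   time_start = 50, time_stop = 150, time_step = 50)
  gt <- truth_with(d, ff = 3, rec = 0, osc = 0, noise_scale = 0.5)
  e <- simulate_eeg_dataset(d, gt, seed = 1)[[1]]
  tc <- decode_timecourse(e, "within-late", n_reps = 3, seed = 2)
  expect_gt(mean(tc$timecourse), 85)
  for (t in seq_along(tc$time_ms)) {
    m <- tc$acc[, , t]
    expect_true(all(is.na(diag(m))))
    expect_equal(m, t(m))
  }
  # same seed reproduces the result exactly
  tc2 <- decode_timecourse(e, "within-late", n_reps = 3, seed = 2)
  expect_identical(tc$acc, tc2$acc)
  expect_error(decode_timecourse(e, "no-such-scheme"), "unknown scheme")
})

test_that("cross-decoding collapses only when mask geometries are disjoint", {
  d <- tiny_design(n_objects = 4, trials_per_cell = 8, n_channels = 16,
                   time_start = 0, time_stop = 200, time_step = 50)
  res <- sapply(c(shared = 1, orthogonal = 0), function(ov) {
    gt <- truth_with(d, osc = 0, rec_by_mask = c(early = 1, late = 1),
                     noise_scale = 0.3, overlap = ov, seed = 1)
    e <- simulate_eeg_dataset(d, gt, seed = 2)[[1]]
    c(within = mean(decode_timecourse(e, "within-late", n_reps = 3,
                                      seed = 3)$timecourse),
      cross = mean(decode_timecourse(e, "cross", n_reps = 3,
                                     seed = 3)$timecourse))
  })
  expect_gt(res["within", "shared"], 80)
  expect_lt(abs(res["cross", "shared"] - res["within", "shared"]), 8)
  expect_gt(res["within", "orthogonal"], 80)
  expect_lt(res["cross", "orthogonal"], 62)
  # within >= cross across a degradation grid of geometry overlap
  within_minus_cross <- sapply(c(0, 0.5, 1), function(ov) {
    gt <- truth_with(d, osc = 0, rec_by_mask = c(early = 1, late = 1),
                     noise_scale = 0.3, overlap = ov, seed = 4)
    e <- simulate_eeg_dataset(d, gt, seed = 5)[[1]]
    mean(decode_timecourse(e, "within-late", n_reps = 2, seed = 6)$timecourse) -
      mean(decode_timecourse(e, "cross", n_reps = 2, seed = 6)$timecourse)
  })
  expect_true(all(within_minus_cross > -5))
})

test_that("missing mask condition aborts cross-decoding", {
  d <- tiny_design(n_objects = 2, trials_per_cell = 4, n_channels = 4,
                   mask_conditions = "early")
  e <- simulate_eeg_dataset(d, truth_with(d, rec_by_mask = c(early = 1)),
                            seed = 1)[[1]]
  expect_error(decode_timecourse(e, "cross"), "both mask conditions")
})

test_that("TGM diagonal matches the time-resolved decoder", {
  d <- tiny_design(n_objects = 3, trials_per_cell = 8, n_channels = 12,
                   time_start = 0, time_stop = 200, time_step = 50)
  gt <- truth_with(d, ff = 1.5, rec = 0, osc = 0, noise_scale = 0.8)
  e <- simulate_eeg_dataset(d, gt, seed = 3)[[1]]
  tg <- temporal_generalization(e, "within-late", n_reps = 8, seed = 4)
  tc <- decode_timecourse(e, "within-late", n_reps = 8, seed = 4)
  expect_equal(tg$values, t(tg$values))
  expect_lt(max(abs(diag(tg$values) - tc$timecourse)), 2)
})

test_that("time-frequency decoding separates power and phase codes", {
  bank <- build_wavelet_bank(f_min = 6, f_max = 20, n = 3,
                             fwhm_max_ms = 300, fwhm_min_ms = 150)
  tt <- seq(-600, 1198, 2)
  n_per <- 8
  set.seed(7)
  make_epochs <- function(code) {
    n_trial <- 2 * n_per
    dat <- array(rnorm(n_trial * 4 * length(tt), sd = 0.3),
                 c(n_trial, 4, length(tt)))
    for (i in seq_len(n_trial)) {
      obj <- (i - 1) %/% n_per + 1
      if (code == "amplitude") {
        amp <- if (obj == 1) 1 else 2.5
        dat[i, , ] <- dat[i, , ] +
          rep(amp * cos(2 * pi * 10 * tt / 1000), each = 4)
      } else {
        phi <- if (obj == 1) 0 else pi
        dat[i, , ] <- dat[i, , ] +
          rep(1.5 * cos(2 * pi * 10 * tt / 1000 + phi), each = 4)
      }
    }
    epoch_set(dat, rep(1:2, each = n_per), rep("early", n_trial), tt)
  }
  for (code in c("amplitude", "phase")) {
    tf <- tfr_transform(make_epochs(code), bank, crop_ms = c(100, 500))
    pw <- timefreq_decode(tf, "power", n_reps = 2, seed = 8)
    ph <- timefreq_decode(tf, "phase", n_reps = 2, seed = 8)
    bin10 <- which.min(abs(pw$freqs_hz - 10))
    if (code == "amplitude") {
      expect_gt(mean(pw$values[, bin10]), 85)
    } else {
      expect_gt(mean(ph$values[, bin10]), 85)
      expect_lt(mean(pw$values[, bin10]), 75)
    }
  }
  tf <- tfr_transform(make_epochs("phase"), bank, crop_ms = c(100, 200))
  expect_error(timefreq_decode(tf, "loudness"), "arg")
})

test_that("ROI decoding groups runs into pseudo-runs correctly", {
  b <- toy_betas(n_runs = 12, k = 4, noise = 0)
  am <- roi_decode(b, n_pseudoruns = 4, seed = 1)
  expect_equal(grand_average(am), 100)       # distinct noiseless patterns
  null_b <- toy_betas(n_runs = 12, k = 4, noise = 0)
  null_b[] <- rnorm(length(null_b))          # pattern-free
  expect_lt(abs(grand_average(roi_decode(null_b, seed = 2)) - 50), 15)
  expect_error(roi_decode(b, n_pseudoruns = 5), "divisible")
})

test_that("searchlight spheres follow the lattice geometry", {
  expect_equal(nrow(sphere_offsets(0)), 1)
  expect_equal(nrow(sphere_offsets(1)), 7)     # center + 6 face neighbors
  expect_equal(nrow(sphere_offsets(4)), sum(outer(outer((-4:4)^2, (-4:4)^2, "+"),
                                                  (-4:4)^2, "+") <= 16))
})

test_that("searchlight localizes a planted informative cube", {
  d <- tiny_design(n_objects = 4, n_runs = 8, n_subjects = 1)
  gt <- truth_with(d, n_layers = 4)
  m <- make_model_rdms(4, n_objects = 4, seed = 1)
  fm <- simulate_fmri_dataset(d, gt, m, seed = 2, noise_scale = 0.4,
                              volume_dim = c(6, 6, 6),
                              signal_cube = c(1, 1, 1, 3))[[1]]
  vol <- fm$volume
  late <- attr(fm$rois[[1]], "conditions")$mask == "late"
  vol_late <- vol[, late, , , , drop = FALSE]
  # average the two presentations per object within run
  conds <- fm$conditions[late, ]
  k <- d$n_objects
  avg <- array(0, c(d$n_runs, k, 6, 6, 6))
  for (o in seq_len(k)) {
    sel <- which(conds$object == o)
    avg[, o, , , ] <- (vol_late[, sel[1], , , ] + vol_late[, sel[2], , , ]) / 2
  }
  sl <- searchlight_decode(avg, fm$mask, radius = 1, n_pseudoruns = 4,
                           seed = 3)
  inside <- sl$values[1:3, 1:3, 1:3]
  outside <- sl$values[5:6, 5:6, 5:6]
  expect_gt(mean(inside), mean(outside) + 15)
  peak <- which(sl$values == max(sl$values), arr.ind = TRUE)[1, ]
  expect_true(all(peak <= 4))
})
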