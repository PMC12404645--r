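test_that("feature RDMs implement 1 - Pearson with an undefined diagonal", {
  f <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  r <- rdm_from_features(f)
  expect_equal(r[1, 2], 0)                      # identical rows
  expect_equal(r[1, 3], 2)                      # anti-correlated rows
  expect_true(all(is.na(diag(r))))
  # hand-computed 3-item example
  g <- rbind(a = c(0, 1, 2, 3), b = c(0, 1, 2, 5), c = c(3, 1, 0, 2))
  rg <- rdm_from_features(g)
  expect_equal(rg[1, 2], 1 - cor(g[1, ], g[2, ]))
  expect_equal(rg[2, 3], 1 - cor(g[2, ], g[3, ]))
  expect_error(rdm_from_features(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})

test_that("RDM correlation is a rank correlation over the lower triangle", {
  set.seed(5)
  a <- rdm_from_features(matrix(rnorm(24), 6, 4))
  expect_equal(rdm_correlate(a, a), 1)
  # rank reversal gives -1
  v <- a[lower.tri(a)]
  bm <- matrix(0, 6, 6)
  bm[lower.tri(bm)] <- max(v) - v
  bm <- bm + t(bm)
  expect_equal(rdm_correlate(a, as_rdm(bm)), -1)
  # brute-force rank-correlation oracle on a 4x4 toy pair
  x <- as_rdm(matrix(c(NA, 1, 2, 3, 1, NA, 4, 5, 2, 4, NA, 6, 3, 5, 6, NA), 4))
  y <- as_rdm(matrix(c(NA, 2, 1, 5, 2, NA, 3, 4, 1, 3, NA, 7, 5, 4, 7, NA), 4))
  vx <- rank(x[lower.tri(x)]); vy <- rank(y[lower.tri(y)])
  oracle <- sum((vx - mean(vx)) * (vy - mean(vy))) /
    sqrt(sum((vx - mean(vx))^2) * sum((vy - mean(vy))^2))
  expect_equal(rdm_correlate(x, y), oracle)
  expect_warning(rdm_correlate(x[1:3, 1:3], y[1:3, 1:3]), "fewer than 4")
  # invariance under monotone transforms
  expect_equal(rdm_correlate(x, y),
               suppressWarnings(rdm_correlate(as_rdm(exp(as.matrix(x))), y)))
})

test_that("noise ceilings bound inter-subject RDM reliability", {
  base <- 1 - cor(matrix(rnorm(40), 8, 5))
  identical_rdms <- replicate(5, as_rdm(base), simplify = FALSE)
  nc <- noise_ceiling(identical_rdms)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  # independent random RDMs: lower bound near zero
  set.seed(6)
  rand <- replicate(20, as_rdm(1 - cor(matrix(rnorm(80), 8, 10))),
                    simplify = FALSE)
  ncr <- noise_ceiling(rand)
  expect_lt(abs(ncr$lower), 0.1)
  expect_lte(ncr$lower, ncr$upper)
  # noisy copies of one geometry: lower <= upper, both substantial
  noisy <- lapply(1:6, function(i)
    as_rdm(base + (1 - cor(matrix(rnorm(40), 8, 5))) * 0.3))
  ncn <- noise_ceiling(noisy)
  expect_lte(ncn$lower, ncn$upper)
  expect_gt(ncn$lower, 0.3)
  expect_error(noise_ceiling(identical_rdms[1:2]), ">= 3")
})

test_that("commonality partitions shared variance like explicit regressions", {
  set.seed(8)
  # target = a = b: all variance shared
  v <- rnorm(15)
  cm <- suppressWarnings(commonality(v, v, v))  # collinear by construction
  expect_equal(cm$shared, 1)
  # orthogonal rank patterns: shared ~ 0
  t0 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  a0 <- t0                                     # target equals predictor a
  b0 <- c(1, -1, 2, -2, 3, -3, 4, -4)          # near-orthogonal ranks
  cm0 <- commonality(t0, a0, b0)
  expect_lt(abs(cm0$shared), 0.05)
  # lm()-based variance-partitioning oracle on arbitrary vectors
  tv <- rnorm(21); av <- tv + rnorm(21); bv <- 0.5 * tv + rnorm(21)
  cm1 <- commonality(tv, av, bv)
  r2 <- function(f) summary(f)$r.squared
  rt <- rank(tv); ra <- rank(av); rb <- rank(bv)
  oracle <- r2(lm(rt ~ ra)) + r2(lm(rt ~ rb)) - r2(lm(rt ~ ra + rb))
  expect_equal(cm1$shared, oracle, tolerance = 1e-10)
  # decomposition identity and symmetry in the predictors
  expect_equal(cm1$shared + cm1$unique_a + cm1$unique_b, cm1$r2_full,
               tolerance = 1e-10)
  cm_sym <- commonality(tv, bv, av)
  expect_equal(cm_sym$shared, cm1$shared, tolerance = 1e-12)
  expect_lte(cm1$shared, min(cm1$r2_a, cm1$r2_b) + 1e-12)
  expect_warning(commonality(tv, av, av), "collinear")
})

test_that("layer-wise RSA timecourse tracks the planted geometry", {
  d <- tiny_design(n_objects = 6, trials_per_cell = 8, n_channels = 30,
                   time_start = 100, time_stop = 200, time_step = 100)
  m <- make_model_rdms(4, n_objects = 6, n_features = 30, seed = 2)
  # EEG patterns built from layer-1 features: RSA should peak at layer 1;
  # noise keeps pairwise accuracies off the 100% ceiling so ranks vary
  gt <- truth_with(d, ff = 0.35, rec = 0, osc = 0, noise_scale = 1.2,
                   seed = 3)
  gt$condition_patterns$feedforward <- lapply(
    gt$condition_patterns$feedforward, function(p) t(m$features[[1]]))
  e <- simulate_eeg_dataset(d, gt, seed = 4)[[1]]
  tc <- decode_timecourse(e, "within-late", n_reps = 3, seed = 5)
  rsa <- rsa_timecourse(tc, m)
  expect_equal(dim(rsa), c(4, 2))
  expect_equal(unname(which.max(rsa[, 1])), 1)
})
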