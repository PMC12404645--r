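test_that("sign-permutation p matches exhaustive enumeration", {
  v <- c(0.5, -0.2, 0.3, 0.1, -0.4, 0.6, 0.2, -0.1, 0.35, 0.15)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  exact <- mean(signs %*% v / 10 >= mean(v) - 1e-12)
  sp <- sign_perm_test(v, n_perm = 10000, seed = 2)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(sp$p - exact), 4 * se)
  # all-positive constant values reach the minimal attainable p
  sp_min <- sign_perm_test(rep(10, 10), n_perm = 2000, seed = 1)
  expect_equal(sp_min$p, 1 / 2000)
  # values symmetric around zero sit near p = 0.5
  sym <- c(-3, -2, -1, 1, 2, 3)
  ps <- sapply(1:20, function(s) sign_perm_test(sym, 2000, seed = s)$p)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_warning(sign_perm_test(v, n_perm = 50), "coarse")
  expect_error(sign_perm_test(1), ">= 2")
})

test_that("permutation p-values are valid under the null", {
  set.seed(77)
  for (alpha in c(0.01, 0.05)) {
    rej <- mean(replicate(400, {
      v <- rnorm(8)
      sign_perm_test(v, n_perm = 500, seed = sample.int(1e6, 1))$p <= alpha
    }))
    se <- sqrt(alpha * (1 - alpha) / 400)
    expect_lte(rej, alpha + 2.5 * se)
  }
})

test_that("cluster inference recovers a planted block and rejects nulls", {
  set.seed(10)
  maps <- matrix(rnorm(12 * 60), 12, 60)
  maps[, 25:40] <- maps[, 25:40] + 1.5
  ci <- cluster_inference(maps, dims = 60, n_perm = 500, seed = 3)
  expect_gte(length(ci$cluster_p), 1)
  expect_lte(min(ci$cluster_p), 0.01)
  sig_idx <- which(ci$sig_mask)
  expect_gt(length(intersect(sig_idx, 25:40)), 10)
  # all-zero maps: empty cluster set, not an error
  ci0 <- cluster_inference(matrix(0, 6, 20), dims = 20, n_perm = 200,
                           seed = 4)
  expect_length(ci0$cluster_p, 0)
  expect_false(any(ci0$sig_mask))
})

test_that("1-D cluster inference equals the 2-D implementation on 1 x N", {
  set.seed(11)
  maps <- matrix(rnorm(8 * 30), 8, 30)
  maps[, 10:18] <- maps[, 10:18] + 1.2
  c1 <- cluster_inference(maps, dims = 30, n_perm = 300, seed = 5)
  c2 <- cluster_inference(maps, dims = c(1, 30), n_perm = 300, seed = 5)
  expect_equal(as.numeric(c1$p_map), as.numeric(c2$p_map))
  expect_equal(c1$cluster_p, c2$cluster_p)
  expect_equal(as.logical(c1$sig_mask), as.logical(c2$sig_mask))
})

test_that("cluster labeling respects orthogonal adjacency in 2-D and 3-D", {
  m2 <- matrix(FALSE, 3, 3)
  m2[1, 1] <- m2[2, 2] <- TRUE              # diagonal touch: two clusters
  lab <- maskmvpa:::label_clusters(m2, c(3, 3))
  expect_equal(max(lab), 2)
  m3 <- array(FALSE, c(3, 3, 3))
  m3[1, 1, 1] <- m3[2, 1, 1] <- m3[2, 2, 1] <- TRUE   # face-connected chain
  expect_equal(max(maskmvpa:::label_clusters(m3, c(3, 3, 3))), 1)
})

test_that("cluster inference controls the family-wise error rate", {
  set.seed(12)
  n_sim <- 200
  fp <- replicate(n_sim, {
    maps <- matrix(rnorm(10 * 40), 10, 40)
    ci <- cluster_inference(maps, dims = 40, n_perm = 500,
                            seed = sample.int(1e6, 1))
    any(ci$cluster_p <= 0.05)
  })
  rate <- mean(fp)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("BH-FDR matches the hand-run step-up rule", {
  p <- c(0.001, 0.011, 0.021, 0.9)
  # sorted p_i <= i * q / m holds for i = 1..3
  expect_equal(fdr_bh(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 5)), rep(FALSE, 5))
  expect_true(fdr_bh(0.04, 0.05))
  expect_length(fdr_bh(numeric(0)), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap peak CIs behave at the degenerate and jittered ends", {
  tt <- seq(0, 400, 20)
  curve <- exp(-(tt - 200)^2 / 2000)
  curves <- matrix(rep(curve, 6), 6, byrow = TRUE)
  ci <- bootstrap_peak_ci(curves, n_boot = 200, x = tt, seed = 1)
  expect_equal(ci$ci, c(200, 200))
  expect_equal(ci$peak, 200)
  # earliest index wins ties
  flatish <- matrix(rep(c(0, 1, 1, 0), 3), 3, byrow = TRUE)
  expect_equal(bootstrap_peak_ci(flatish, n_boot = 50, seed = 2)$peak, 2)
  expect_warning(bootstrap_peak_ci(matrix(1, 3, 5), n_boot = 50, seed = 3),
                 "flat")
  # CI width grows with peak jitter
  width <- sapply(c(20, 80), function(jit) {
    set.seed(jit)
    cs <- t(sapply(1:12, function(s)
      exp(-(tt - (200 + runif(1, -jit, jit)))^2 / 2000)))
    ci <- bootstrap_peak_ci(cs, n_boot = 300, x = tt, seed = 4)
    diff(ci$ci)
  })
  expect_lte(width[1], width[2])
})

test_that("peak-shift permutation test matches enumeration, g is corrected", {
  set.seed(13)
  a <- rnorm(10); b <- a - 0.8 + rnorm(10, sd = 0.3)
  d <- a - b
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  exact <- mean(abs(signs %*% d / 10) >= abs(mean(d)) - 1e-12)
  ps <- peak_shift_test(a, b, n_perm = 10000, seed = 6)
  se <- sqrt(max(exact, 1e-4) * (1 - exact) / 10000)
  expect_lt(abs(ps$p - exact), 4 * se + 1e-3)
  # identical conditions: p ~ 1, g = 0
  ps0 <- peak_shift_test(a, a, n_perm = 1000, seed = 7)
  expect_equal(ps0$p, 1)
  expect_equal(ps0$g, 0)
  # Hedges correction shrinks Cohen's d
  expect_equal(hedges_g(d), mean(d) / sd(d) * (1 - 3 / (4 * 9 - 1)))
  expect_error(peak_shift_test(1:2, 2:3), ">= 3")
})
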