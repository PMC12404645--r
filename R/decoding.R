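#' @title Pairwise linear decoding machinery
#' @description Internal SVM helpers plus the user-facing decoding analyses:
#'   time-resolved pairwise decoding within/across masking conditions,
#'   temporal generalization, time-frequency decoding, ROI and searchlight
#'   decoding of fMRI betas, and pair-subset aggregation.
#' @name decoding
NULL

# Fit a linear max-margin classifier (LIBSVM via e1071, cost = 1, no
# scaling) and return the hyperplane (w, b) with the orientation convention
# that class "a" (first block of rows) has positive decision values.
svm_hyperplane <- function(x_a, x_b, cost = 1) {
  x <- rbind(x_a, x_b)
  y <- factor(rep(c("a", "b"), c(nrow(x_a), nrow(x_b))))
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient so the training mean of class "a" is on the positive side
  if (mean(x_a %*% w + b) < mean(x_b %*% w + b)) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

# Leave-one-pseudo-trial-out pairwise accuracy for two n_pseudo x p matrices.
pair_loo_accuracy <- function(pa, pb, cost = 1) {
  n <- nrow(pa)
  if (n < 2) stop("need at least 2 pseudo-trials per class")
  correct <- 0L
  for (f in seq_len(n)) {
    hp <- svm_hyperplane(pa[-f, , drop = FALSE], pb[-f, , drop = FALSE], cost)
    correct <- correct + (sum(pa[f, ] * hp$w) + hp$b > 0) +
      (sum(pb[f, ] * hp$w) + hp$b < 0)
  }
  100 * correct / (2 * n)
}

#' Bin trials into averaged pseudo-trials
#'
#' Randomly partitions the trials of one condition into `n_bins` equally
#' sized bins and averages within each bin, raising the SNR before
#' classification. Surplus trials (`n %% n_bins`) are dropped uniformly at
#' random. Randomness comes from the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param x Trials of one condition: a trial x feature matrix or a trial x
#'   (any further dims) array.
#' @param n_bins Number of pseudo-trials to form (default 4).
#' @return Array with `n_bins` leading entries and the remaining dims of `x`;
#'   the bin assignment is attached as attribute `"assignment"` (0 = dropped).
#' @examples
#' set.seed(1)
#' p <- bin_pseudotrials(matrix(rnorm(53 * 4), 53, 4))
#' table(attr(p, "assignment"))  # bins of 13, one trial dropped
#' @export
bin_pseudotrials <- function(x, n_bins = 4) {
  was_matrix <- is.matrix(x)
  n <- dim(x)[1]
  if (n < n_bins) stop("fewer trials (", n, ") than bins (", n_bins, ")")
  per_bin <- n %/% n_bins
  assignment <- integer(n)
  kept <- sample.int(n, per_bin * n_bins)
  assignment[kept] <- rep(seq_len(n_bins), each = per_bin)
  rest_dim <- dim(x)[-1]
  flat <- matrix(x, n, prod(rest_dim))
  out_flat <- matrix(0, n_bins, prod(rest_dim))
  for (b in seq_len(n_bins)) {
    out_flat[b, ] <- colMeans(flat[assignment == b, , drop = FALSE])
  }
  out <- if (was_matrix) out_flat else array(out_flat, c(n_bins, rest_dim))
  attr(out, "assignment") <- assignment
  out
}

#' Pairwise decoding accuracy between two pseudo-trial sets
#'
#' Leave-one-pseudo-trial-out cross-validation: each fold trains a linear
#' max-margin classifier on all but one pseudo-trial per class and tests on
#' the held-out pair.
#'
#' @param pseudo_a,pseudo_b Pseudo-trial x feature matrices, equal row count.
#' @param cost SVM regularization constant.
#' @return Percent correct (chance 50).
#' @export
pairwise_accuracy <- function(pseudo_a, pseudo_b, cost = 1) {
  if (nrow(pseudo_a) != nrow(pseudo_b))
    stop("classes must have equal pseudo-trial counts")
  if (nrow(pseudo_a) < 2) stop("need more than one pseudo-trial per class")
  pair_loo_accuracy(pseudo_a, pseudo_b, cost)
}

#' K x K accuracy matrix
#'
#' Symmetric matrix of pairwise percent-correct decoding accuracies with an
#' undefined (NA) diagonal; doubles as a neural RDM downstream.
#'
#' @param values Symmetric numeric matrix, entries in `[0, 100]`.
#' @return Object of class `accuracy_matrix`.
#' @export
accuracy_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  diag(values) <- NA
  if (!isTRUE(all.equal(values, t(values)))) stop("accuracy matrix must be symmetric")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100) stop("accuracies must lie in [0, 100]")
  structure(values, class = c("accuracy_matrix", "matrix"))
}

#' Grand-average accuracy over off-diagonal cells
#' @param m An accuracy matrix (diagonal NA) or array of them.
#' @return Mean over defined cells.
#' @export
grand_average <- function(m) mean(m, na.rm = TRUE)

#' Average selected condition pairs of an accuracy matrix
#'
#' Aggregates a subset of cells, e.g., only pairs that cross a categorical
#' boundary (naturalness, animacy), into one summary accuracy.
#'
#' @param m K x K accuracy matrix (diagonal ignored).
#' @param pair_mask Symmetric logical K x K matrix selecting pairs.
#' @return Mean accuracy over the selected off-diagonal cells.
#' @examples
#' m <- matrix(60, 4, 4); diag(m) <- NA
#' between <- outer(1:4, 1:4, function(i, j) (i <= 2) != (j <= 2))
#' aggregate_pairs(m, between)
#' @export
aggregate_pairs <- function(m, pair_mask) {
  stopifnot(is.matrix(pair_mask), all(dim(pair_mask) == dim(m)))
  if (!isTRUE(all(pair_mask == t(pair_mask)))) stop("pair_mask must be symmetric")
  sel <- pair_mask & row(m) != col(m)
  if (!any(sel)) stop("pair_mask selects no off-diagonal cells")
  mean(m[sel])
}

# Pseudo-trial array (object x bin x feature x time) for one mask condition,
# drawn fresh from the current RNG state. features = channels here.
draw_pseudo <- function(epochs, mask, n_bins) {
  objects <- sort(unique(epochs$object_label))
  d <- dim(epochs$data)
  out <- array(0, c(length(objects), n_bins, d[2], d[3]))
  for (i in seq_along(objects)) {
    idx <- which(epochs$object_label == objects[i] & epochs$mask_label == mask)
    out[i, , , ] <- bin_pseudotrials(epochs$data[idx, , , drop = FALSE], n_bins)
  }
  out
}

scheme_masks <- function(epochs, scheme) {
  masks <- unique(epochs$mask_label)
  pick <- function(m) {
    if (!m %in% masks) stop("mask condition '", m, "' absent from the data")
    m
  }
  switch(scheme,
    "within-early" = list(train = pick("early"), test = pick("early")),
    "within-late"  = list(train = pick("late"),  test = pick("late")),
    "cross" = {
      if (length(masks) < 2) stop("cross-decoding needs both mask conditions")
      list(train = pick("early"), test = pick("late"))
    },
    stop("unknown scheme: ", scheme))
}

#' Time-resolved pairwise decoding
#'
#' At each time point, decodes every pair of object conditions from channel
#' patterns with leave-one-pseudo-trial-out cross-validation, repeated
#' `n_reps` times with fresh random pseudo-trial assignments, and averages
#' over repetitions. Within-condition schemes train and test inside one
#' masking condition; the cross scheme trains on one masking condition and
#' tests on the other, averaged over both directions (pseudo-trials are
#' re-drawn independently per direction and repetition).
#'
#' @param epochs An [epoch_set()].
#' @param scheme `"within-early"`, `"within-late"`, or `"cross"`.
#' @param n_reps Pseudo-trial assignment repetitions (the reference analysis
#'   uses 100).
#' @param n_bins Pseudo-trials per condition.
#' @param cost SVM regularization constant.
#' @param seed Integer seed.
#' @return Object of class `decoding_timecourse`: `acc` (K x K x time array,
#'   diagonal NA), `time_ms`, `timecourse` (grand average per time point),
#'   `scheme`.
#' @export
decode_timecourse <- function(epochs, scheme = "within-early", n_reps = 100,
                              n_bins = 4, cost = 1, seed = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  sm <- scheme_masks(epochs, scheme)
  set.seed(seed)
  objects <- sort(unique(epochs$object_label))
  k <- length(objects)
  n_time <- dim(epochs$data)[3]
  acc <- array(0, c(k, k, n_time))
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  directions <- if (scheme == "cross") {
    list(c(sm$train, sm$test), c(sm$test, sm$train))
  } else list(c(sm$train, sm$test))
  for (rep_i in seq_len(n_reps)) {
    for (dir in directions) {
      p_tr <- draw_pseudo(epochs, dir[1], n_bins)
      p_te <- if (dir[1] == dir[2]) p_tr else draw_pseudo(epochs, dir[2], n_bins)
      for (t in seq_len(n_time)) {
        for (pr in seq_len(nrow(pairs))) {
          i <- pairs[pr, 1]; j <- pairs[pr, 2]
          a <- cv_pair_accuracy(p_tr[i, , , t], p_tr[j, , , t],
                                p_te[i, , , t], p_te[j, , , t], cost)
          acc[i, j, t] <- acc[i, j, t] + a
        }
      }
    }
  }
  acc <- acc / (n_reps * length(directions))
  for (t in seq_len(n_time)) {
    m <- acc[, , t]
    acc[, , t] <- m + t(m)
    diag(acc[, , t]) <- NA
  }
  structure(list(acc = acc, time_ms = epochs$time_ms,
                 timecourse = apply(acc, 3, mean, na.rm = TRUE),
                 scheme = scheme, n_reps = n_reps),
            class = "decoding_timecourse")
}

# One cross-validated pair accuracy where train and test pseudo-trial sets
# may come from different conditions (or be the same object).
cv_pair_accuracy <- function(tr_a, tr_b, te_a, te_b, cost = 1) {
  n <- nrow(tr_a)
  correct <- 0L
  for (f in seq_len(n)) {
    hp <- svm_hyperplane(tr_a[-f, , drop = FALSE], tr_b[-f, , drop = FALSE],
                         cost)
    correct <- correct + (sum(te_a[f, ] * hp$w) + hp$b > 0) +
      (sum(te_b[f, ] * hp$w) + hp$b < 0)
  }
  100 * correct / (2 * n)
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat("Decoding timecourse (", x$scheme, "): ", dim(x$acc)[1], " conditions x ",
      length(x$time_ms), " time points, ", x$n_reps, " reps\n", sep = "")
  cat("  grand average: ", round(mean(x$timecourse), 2), "% (peak ",
      round(max(x$timecourse), 2), "% at ",
      x$time_ms[which.max(x$timecourse)], " ms)\n", sep = "")
  invisible(x)
}

#' Temporal generalization analysis
#'
#' Trains the pairwise classifiers at each time point and tests them at every
#' time point, yielding a train-time x test-time matrix of grand-average
#' accuracies. Because train and test directions carry no meaning, the TGM is
#' symmetrized by averaging both directions. Diagonal dominance indicates
#' transient codes; off-diagonal spread indicates persistent codes; and
#' below-chance off-diagonal cells arise from phase-shifted oscillatory
#' codes tested at half-cycle offsets.
#'
#' @inheritParams decode_timecourse
#' @param symmetrize Average the two train/test directions (default TRUE).
#' @return Object of class `tgm`: `values` (train x test grand-average
#'   accuracy), `time_ms`, `symmetrized`.
#' @export
temporal_generalization <- function(epochs, scheme = "within-early",
                                    n_reps = 20, n_bins = 4, cost = 1,
                                    seed = 1, symmetrize = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  sm <- scheme_masks(epochs, scheme)
  set.seed(seed)
  objects <- sort(unique(epochs$object_label))
  k <- length(objects)
  n_time <- dim(epochs$data)[3]
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  tgm <- matrix(0, n_time, n_time)
  directions <- if (scheme == "cross") {
    list(c(sm$train, sm$test), c(sm$test, sm$train))
  } else list(c(sm$train, sm$test))
  n_bins_seq <- seq_len(n_bins)
  for (rep_i in seq_len(n_reps)) {
    for (dir in directions) {
      p_tr <- draw_pseudo(epochs, dir[1], n_bins)
      p_te <- if (dir[1] == dir[2]) p_tr else draw_pseudo(epochs, dir[2], n_bins)
      for (t in seq_len(n_time)) {
        for (pr in seq_len(nrow(pairs))) {
          i <- pairs[pr, 1]; j <- pairs[pr, 2]
          n_chan <- dim(p_tr)[3]
          for (f in n_bins_seq) {
            hp <- svm_hyperplane(matrix(p_tr[i, -f, , t], ncol = n_chan),
                                 matrix(p_tr[j, -f, , t], ncol = n_chan), cost)
            # decision values of the held-out pseudo-trials at all test times
            d_a <- crossprod(matrix(p_te[i, f, , ], ncol = n_time), hp$w) + hp$b
            d_b <- crossprod(matrix(p_te[j, f, , ], ncol = n_time), hp$w) + hp$b
            tgm[t, ] <- tgm[t, ] + as.numeric(d_a > 0) + as.numeric(d_b < 0)
          }
        }
      }
    }
  }
  tgm <- 100 * tgm / (n_reps * length(directions) * nrow(pairs) * n_bins * 2)
  if (symmetrize) tgm <- (tgm + t(tgm)) / 2
  structure(list(values = tgm, time_ms = epochs$time_ms,
                 symmetrized = symmetrize, scheme = scheme),
            class = "tgm")
}

#' @export
print.tgm <- function(x, ...) {
  cat("TGM (", x$scheme, if (x$symmetrized) ", symmetrized" else "", "): ",
      nrow(x$values), " x ", ncol(x$values), " time points, grand mean ",
      round(mean(x$values), 2), "%\n", sep = "")
  invisible(x)
}

#' Time-frequency-resolved decoding
#'
#' Decodes object identity from spectral features at each time point and
#' frequency: per-channel power values (feature dimension = channels) or the
#' concatenated cosine/sine phase pair (feature dimension = 2 x channels;
#' 128 for a 64-channel montage).
#'
#' @param tfr A [tfr_transform()] result.
#' @param feature `"power"` or `"phase"`.
#' @inheritParams decode_timecourse
#' @return Object of class `tf_map`: `values` (time x frequency grand-average
#'   accuracy), `time_ms`, `freqs_hz`, `feature`, plus `acc` (K x K x freq x
#'   time accuracy matrices) when `return_matrices = TRUE`.
#' @param return_matrices Keep the per-pair accuracy matrices.
#' @export
timefreq_decode <- function(tfr, feature = c("power", "phase"),
                            scheme = "within-early", n_reps = 5, n_bins = 4,
                            cost = 1, seed = 1, return_matrices = FALSE) {
  stopifnot(inherits(tfr, "tfr_set"))
  feature <- match.arg(feature)
  feats <- if (feature == "power") tfr_power(tfr) else tfr_phase(tfr)
  feats[is.na(feats)] <- 0   # undefined phase (zero power) carries no signal
  d <- dim(feats)            # trial x feature x freq x time
  n_freq <- d[3]; n_time <- d[4]
  sm <- scheme_masks_labels(tfr$mask_label, scheme)
  set.seed(seed)
  objects <- sort(unique(tfr$object_label))
  k <- length(objects)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  acc <- array(0, c(k, k, n_freq, n_time))
  directions <- if (scheme == "cross") {
    list(c(sm$train, sm$test), c(sm$test, sm$train))
  } else list(c(sm$train, sm$test))
  draw <- function(mask, fi) {
    out <- array(0, c(k, n_bins, d[2], n_time))
    for (i in seq_along(objects)) {
      idx <- which(tfr$object_label == objects[i] & tfr$mask_label == mask)
      out[i, , , ] <- bin_pseudotrials(feats[idx, , fi, , drop = FALSE][, , 1, ],
                                       n_bins)
    }
    out
  }
  for (fi in seq_len(n_freq)) {
    for (rep_i in seq_len(n_reps)) {
      for (dir in directions) {
        p_tr <- draw(dir[1], fi)
        p_te <- if (dir[1] == dir[2]) p_tr else draw(dir[2], fi)
        for (t in seq_len(n_time)) for (pr in seq_len(nrow(pairs))) {
          i <- pairs[pr, 1]; j <- pairs[pr, 2]
          acc[i, j, fi, t] <- acc[i, j, fi, t] +
            cv_pair_accuracy(p_tr[i, , , t], p_tr[j, , , t],
                             p_te[i, , , t], p_te[j, , , t], cost)
        }
      }
    }
  }
  acc <- acc / (n_reps * length(directions))
  map <- matrix(0, n_time, n_freq)
  for (fi in seq_len(n_freq)) for (t in seq_len(n_time)) {
    m <- acc[, , fi, t]
    map[t, fi] <- mean(m[upper.tri(m)])
  }
  out <- list(values = map, time_ms = tfr$time_ms, freqs_hz = tfr$freqs_hz,
              feature = feature, scheme = scheme)
  if (return_matrices) out$acc <- acc
  structure(out, class = "tf_map")
}

scheme_masks_labels <- function(mask_label, scheme) {
  masks <- unique(mask_label)
  pick <- function(m) {
    if (!m %in% masks) stop("mask condition '", m, "' absent from the data")
    m
  }
  switch(scheme,
    "within-early" = list(train = pick("early"), test = pick("early")),
    "within-late"  = list(train = pick("late"),  test = pick("late")),
    "cross" = {
      if (length(masks) < 2) stop("cross-decoding needs both mask conditions")
      list(train = pick("early"), test = pick("late"))
    },
    stop("unknown scheme: ", scheme))
}

#' @export
print.tf_map <- function(x, ...) {
  cat("Time-frequency decoding map (", x$feature, ", ", x$scheme, "): ",
      nrow(x$values), " time x ", ncol(x$values), " frequency, grand mean ",
      round(mean(x$values), 2), "%\n", sep = "")
  invisible(x)
}

#' ROI decoding of fMRI run-wise patterns
#'
#' Groups runs into pseudo-runs (e.g., 12 runs into 4 pseudo-runs of 3),
#' averages patterns within each group, and decodes every condition pair in
#' a leave-one-pseudo-run-out manner.
#'
#' @param betas run x condition x voxel array.
#' @param n_pseudoruns Number of pseudo-runs; the run count must be divisible
#'   by it.
#' @param cost SVM regularization constant.
#' @param seed Integer seed for the random run grouping.
#' @return An [accuracy_matrix()] (K x K).
#' @export
roi_decode <- function(betas, n_pseudoruns = 4, cost = 1, seed = 1) {
  d <- dim(betas)
  if (length(d) != 3) stop("betas must be run x condition x voxel")
  if (d[1] %% n_pseudoruns != 0)
    stop(d[1], " runs are not divisible into ", n_pseudoruns, " pseudo-runs")
  set.seed(seed)
  acc <- roi_decode_core(betas, n_pseudoruns, cost)
  accuracy_matrix(acc)
}

# Core without seeding/validation, reusable by the searchlight.
roi_decode_core <- function(betas, n_pseudoruns, cost) {
  d <- dim(betas)
  per <- d[1] %/% n_pseudoruns
  grouping <- sample(rep(seq_len(n_pseudoruns), per))
  pseudo <- array(0, c(n_pseudoruns, d[2], d[3]))
  for (g in seq_len(n_pseudoruns)) {
    pseudo[g, , ] <- apply(betas[grouping == g, , , drop = FALSE], c(2, 3), mean)
  }
  k <- d[2]
  acc <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- pair_loo_accuracy(matrix(pseudo[, i, ], n_pseudoruns, d[3]),
                           matrix(pseudo[, j, ], n_pseudoruns, d[3]), cost)
    acc[i, j] <- a; acc[j, i] <- a
  }
  acc
}

#' Sphere offsets for a searchlight radius
#' @param radius Radius in voxel units (Euclidean, center included).
#' @return Integer matrix of x/y/z offsets.
#' @export
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Volumetric searchlight decoding
#'
#' For each voxel inside the brain mask, decodes object identity from the
#' patterns in a sphere of voxels around it (Euclidean radius in voxel
#' units, center included; spheres are truncated at mask edges) and stores
#' the grand-average accuracy at the center voxel.
#'
#' @param volume run x condition x x x y x z beta array.
#' @param mask Logical 3-D array (voxels outside remain NA).
#' @param radius Sphere radius in voxels (reference analysis: 4).
#' @param n_pseudoruns Pseudo-runs for [roi_decode()].
#' @param cost SVM regularization constant.
#' @param seed Integer seed (one run grouping shared by all spheres).
#' @return Object of class `searchlight_map`: `values` (3-D accuracy array,
#'   NA outside the mask), `radius`.
#' @export
searchlight_decode <- function(volume, mask, radius = 4, n_pseudoruns = 4,
                               cost = 1, seed = 1) {
  d <- dim(volume)
  if (length(d) != 5) stop("volume must be run x condition x x x y x z")
  vd <- d[3:5]
  stopifnot(all(dim(mask) == vd))
  if (d[1] %% n_pseudoruns != 0)
    stop(d[1], " runs are not divisible into ", n_pseudoruns, " pseudo-runs")
  offs <- sphere_offsets(radius)
  flat <- array(volume, c(d[1], d[2], prod(vd)))
  out <- array(NA_real_, vd)
  centers <- which(mask, arr.ind = TRUE)
  set.seed(seed)
  for (ci in seq_len(nrow(centers))) {
    ctr <- centers[ci, ]
    vox <- sweep(offs, 2, ctr, "+")
    ok <- vox[, 1] >= 1 & vox[, 1] <= vd[1] &
      vox[, 2] >= 1 & vox[, 2] <= vd[2] &
      vox[, 3] >= 1 & vox[, 3] <= vd[3]
    vox <- vox[ok, , drop = FALSE]
    idx <- (vox[, 3] - 1) * vd[1] * vd[2] + (vox[, 2] - 1) * vd[1] + vox[, 1]
    idx <- idx[mask[idx]]
    if (!length(idx)) next
    acc <- roi_decode_core(flat[, , idx, drop = FALSE], n_pseudoruns, cost)
    out[ctr[1], ctr[2], ctr[3]] <- mean(acc[upper.tri(acc)])
  }
  structure(list(values = out, radius = radius), class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  cat("Searchlight map:", paste(dim(x$values), collapse = " x "),
      "voxels, radius", x$radius, "\n")
  cat("  accuracy range:", paste(round(range(x$values, na.rm = TRUE), 1),
                                 collapse = " - "), "%\n")
  invisible(x)
}
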