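#' Ground truth for the synthetic generator
#'
#' Encodes the generative model behind the synthetic EEG/fMRI data: a
#' transient feedforward component, a persistent "recurrent" component whose
#' amplitude depends on the masking condition (the early mask curtails it, the
#' late mask spares it), a stimulus-locked oscillatory component whose phase
#' carries object identity, spatially correlated Gaussian noise, and per-ROI
#' mixing weights over model layers that set each ROI's representational
#' geometry.
#'
#' Setting all three amplitudes to zero yields data that carries no condition
#' information, so every downstream decoding statistic should sit at chance.
#'
#' @param design A [design_spec()].
#' @param feedforward List with `peak_ms`, `fwhm_ms`, `amplitude` — a Gaussian
#'   transient shared by both masking conditions.
#' @param recurrent List with `onset_ms`, `plateau_ms`, `amplitude`, and
#'   `amplitude_by_mask` (named multipliers per mask condition) — a sustained
#'   plateau starting after the feedforward sweep.
#' @param oscillatory List with `freq_hz`, `amplitude`, `onset_ms` — a
#'   phase-locked oscillation whose per-object phase is drawn uniformly on
#'   `[0, 2*pi)`.
#' @param noise List with `rho` (AR(1) channel correlation) and `scale`
#'   (standard deviation); noise is temporally white and spatially correlated.
#' @param roi_geometry Named list: per ROI, a named list over mask conditions
#'   of non-negative mixing-weight vectors over model layers. `NULL` keeps the
#'   default two-ROI geometry (an entry-level ROI tied to a shallow layer in
#'   both conditions; an object-selective ROI tied to a middle layer under the
#'   early mask and to the deepest layer under the late mask).
#' @param n_layers Number of model layers the ROI geometry refers to.
#' @param pattern_overlap Overlap in `[0, 1]` between the condition patterns
#'   of the two masking conditions: 1 (default) means both conditions share
#'   one representational geometry (cross-condition decoding matches
#'   within-condition decoding in expectation); 0 means fully mask-specific,
#'   orthogonal geometries (cross-condition decoding falls to chance while
#'   within-condition decoding stays high).
#' @param subject_jitter_sd Standard deviation of per-subject pattern jitter
#'   around the shared population patterns (makes group statistics and noise
#'   ceilings meaningful).
#' @param seed Integer seed for drawing the population-level patterns/phases.
#' @return An object of class `ground_truth`.
#' @examples
#' d <- design_spec(n_objects = 8, trials_per_cell = 12)
#' gt <- ground_truth(d, seed = 1)
#' @export
ground_truth <- function(design,
                         feedforward = list(peak_ms = 120, fwhm_ms = 100, amplitude = 1),
                         recurrent = list(onset_ms = 150, plateau_ms = 450, amplitude = 0.8,
                                          amplitude_by_mask = c(early = 0.2, late = 1)),
                         oscillatory = list(freq_hz = 10, amplitude = 0.5, onset_ms = 50),
                         noise = list(rho = 0.3, scale = 1),
                         roi_geometry = NULL,
                         n_layers = 8,
                         pattern_overlap = 1,
                         subject_jitter_sd = 0.2,
                         seed = 1) {
  stopifnot(inherits(design, "design_spec"))
  amps <- c(feedforward$amplitude, recurrent$amplitude, oscillatory$amplitude,
            recurrent$amplitude_by_mask, noise$scale)
  if (any(amps < 0)) stop("amplitudes must be non-negative")
  missing_mask <- setdiff(design$mask_conditions, names(recurrent$amplitude_by_mask))
  if (length(missing_mask))
    stop("amplitude_by_mask lacks mask condition(s): ", paste(missing_mask, collapse = ", "))
  if (is.null(roi_geometry)) roi_geometry <- default_roi_geometry(design, n_layers)
  for (roi in roi_geometry) for (w in roi) {
    if (length(w) != n_layers || any(w < 0))
      stop("roi_geometry weights must be non-negative vectors of length n_layers")
  }
  if (pattern_overlap < 0 || pattern_overlap > 1)
    stop("pattern_overlap must lie in [0, 1]")
  set.seed(seed)
  nc <- design$n_channels; no <- design$n_objects
  # per-mask patterns: sqrt(overlap) * shared + sqrt(1 - overlap) * specific
  draw_masked <- function() {
    shared <- matrix(stats::rnorm(nc * no), nc, no)
    stats::setNames(lapply(design$mask_conditions, function(m)
      sqrt(pattern_overlap) * shared +
        sqrt(1 - pattern_overlap) * matrix(stats::rnorm(nc * no), nc, no)),
      design$mask_conditions)
  }
  structure(list(
    condition_patterns = list(
      feedforward = draw_masked(),
      recurrent   = draw_masked()
    ),
    oscillatory_topography = stats::rnorm(nc),
    feedforward_component = feedforward,
    recurrent_component = recurrent,
    oscillatory_component = c(oscillatory,
                              list(phase_by_object = stats::runif(no, 0, 2 * pi))),
    noise = noise,
    roi_geometry = roi_geometry,
    n_layers = as.integer(n_layers),
    pattern_overlap = pattern_overlap,
    subject_jitter_sd = subject_jitter_sd,
    n_channels = nc, n_objects = no
  ), class = "ground_truth")
}

default_roi_geometry <- function(design, n_layers) {
  peaked <- function(at) {
    w <- rep(0, n_layers)
    w[at] <- 1
    if (at > 1) w[at - 1] <- 0.3
    if (at < n_layers) w[at + 1] <- 0.3
    w
  }
  shallow <- min(2L, n_layers)
  mid <- max(1L, round(n_layers / 2))
  masks <- design$mask_conditions
  g <- list(
    EVC = stats::setNames(rep(list(peaked(shallow)), length(masks)), masks),
    LOC = stats::setNames(lapply(masks, function(m)
      if (m == "early") peaked(mid) else peaked(n_layers)), masks)
  )
  g
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("GroundTruth:", x$n_objects, "objects,", x$n_channels, "channels\n")
  cat("  feedforward: peak", x$feedforward_component$peak_ms, "ms, amp",
      x$feedforward_component$amplitude, "\n")
  cat("  recurrent: onset", x$recurrent_component$onset_ms, "ms, amp by mask [",
      paste(sprintf("%s=%g", names(x$recurrent_component$amplitude_by_mask),
                    x$recurrent_component$amplitude_by_mask *
                      x$recurrent_component$amplitude), collapse = ", "), "]\n")
  cat("  oscillatory:", x$oscillatory_component$freq_hz, "Hz, amp",
      x$oscillatory_component$amplitude, "\n")
  cat("  ROIs:", paste(names(x$roi_geometry), collapse = ", "),
      "over", x$n_layers, "layers\n")
  invisible(x)
}

#' Layered model RDMs with smoothly shifting geometry
#'
#' Builds an ordered set of representational dissimilarity matrices standing
#' in for the layers of a deep network trained on object categorization:
#' ascending layers capture features of increasing complexity, so the
#' representational geometry shifts smoothly from a "shallow" basis to a
#' "deep" basis. Each layer's feature matrix is a rotation between two
#' orthogonalized random bases, and its RDM is 1 - Pearson correlation over
#' feature rows; adjacent layers therefore correlate more strongly than
#' distant ones.
#'
#' @param n_layers Number of layers (>= 2).
#' @param n_objects Number of object conditions.
#' @param n_features Feature dimensionality per layer.
#' @param seed Integer seed.
#' @return An object of class `model_rdm_set`: a list with `rdms` (per-layer
#'   K x K matrices of class `rdm`) and `features` (per-layer object x
#'   feature matrices, used by the fMRI simulator to plant ROI geometry).
#' @examples
#' m <- make_model_rdms(n_layers = 8, n_objects = 12, seed = 1)
#' rdm_correlate(m$rdms[[1]], m$rdms[[2]]) > rdm_correlate(m$rdms[[1]], m$rdms[[8]])
#' @export
make_model_rdms <- function(n_layers, n_objects = 24, n_features = 40, seed = 1) {
  if (n_layers < 2) stop("n_layers must be >= 2")
  set.seed(seed)
  g1 <- matrix(stats::rnorm(n_objects * n_features), n_objects, n_features)
  g2 <- matrix(stats::rnorm(n_objects * n_features), n_objects, n_features)
  theta <- seq(0, pi / 2, length.out = n_layers)
  features <- lapply(theta, function(th) cos(th) * g1 + sin(th) * g2)
  rdms <- lapply(features, rdm_from_features)
  structure(list(rdms = rdms, features = features, n_layers = as.integer(n_layers),
                 n_objects = as.integer(n_objects)),
            class = "model_rdm_set")
}

#' @export
print.model_rdm_set <- function(x, ...) {
  cat("ModelRDMSet:", x$n_layers, "layers,", x$n_objects, "objects\n")
  invisible(x)
}

# Time-course envelopes of the signal components (time in ms).
envelope_feedforward <- function(time_ms, comp) {
  exp(-4 * log(2) * (time_ms - comp$peak_ms)^2 / comp$fwhm_ms^2)
}

envelope_recurrent <- function(time_ms, comp) {
  stats::plogis((time_ms - comp$onset_ms) / 25) *
    stats::plogis((comp$onset_ms + comp$plateau_ms - time_ms) / 50)
}

envelope_oscillatory <- function(time_ms, comp) {
  stats::plogis((time_ms - comp$onset_ms) / 25)
}

# Noiseless chan x time template for one object in one mask condition,
# given subject-level patterns.
signal_template <- function(truth, patterns, object, mask, time_ms) {
  ff <- truth$feedforward_component
  rc <- truth$recurrent_component
  os <- truth$oscillatory_component
  tmpl <- ff$amplitude * patterns$feedforward[[mask]][, object] %o%
    envelope_feedforward(time_ms, ff)
  rec_amp <- rc$amplitude * rc$amplitude_by_mask[[mask]]
  if (rec_amp > 0)
    tmpl <- tmpl + rec_amp * patterns$recurrent[[mask]][, object] %o%
      envelope_recurrent(time_ms, rc)
  if (os$amplitude > 0) {
    carrier <- cos(2 * pi * os$freq_hz * time_ms / 1000 +
                     os$phase_by_object[object]) *
      envelope_oscillatory(time_ms, os)
    tmpl <- tmpl + os$amplitude * patterns$oscillatory %o% carrier
  }
  tmpl
}

subject_patterns <- function(truth) {
  jit <- truth$subject_jitter_sd
  jitter_masked <- function(pm) {
    lapply(pm, function(p)
      p + matrix(stats::rnorm(length(p), sd = jit), nrow(p), ncol(p)))
  }
  list(
    feedforward = jitter_masked(truth$condition_patterns$feedforward),
    recurrent = jitter_masked(truth$condition_patterns$recurrent),
    oscillatory = truth$oscillatory_topography +
      stats::rnorm(truth$n_channels, sd = jit)
  )
}

# Cholesky factor of the AR(1) channel covariance.
noise_chol <- function(n_channels, rho) {
  sigma <- rho^abs(outer(seq_len(n_channels), seq_len(n_channels), "-"))
  chol(sigma)
}

#' Simulate a multi-subject EEG dataset
#'
#' Draws per-subject epoch sets under the generative model in a
#' [ground_truth()]: per-object signal templates (feedforward transient +
#' mask-dependent persistent component + phase-coded oscillation) plus
#' temporally white, spatially correlated Gaussian noise. Subject-specific
#' patterns are the shared population patterns plus jitter.
#'
#' @param design A [design_spec()].
#' @param truth A [ground_truth()] whose channel/object dimensions match the
#'   design.
#' @param seed Integer seed; the same seed reproduces the dataset bit-exactly.
#' @param time_ms Optional alternative epoch grid (e.g., a longer, finer grid
#'   for wavelet analyses); defaults to the design's grid.
#' @return A list of `epoch_set` objects, one per subject.
#' @examples
#' d <- design_spec(n_objects = 4, trials_per_cell = 8, n_channels = 16,
#'                  n_subjects = 2)
#' eeg <- simulate_eeg_dataset(d, ground_truth(d, seed = 1), seed = 2)
#' eeg[[1]]
#' @export
simulate_eeg_dataset <- function(design, truth, seed = 1, time_ms = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "ground_truth"))
  if (truth$n_channels != design$n_channels || truth$n_objects != design$n_objects)
    stop("ground_truth dimensions do not match the design")
  if (is.null(time_ms)) time_ms <- design$time_ms
  set.seed(seed)
  n_time <- length(time_ms)
  nc <- design$n_channels
  masks <- design$mask_conditions
  cells <- expand.grid(object = seq_len(design$n_objects), mask = masks,
                       stringsAsFactors = FALSE)
  n_trial <- nrow(cells) * design$trials_per_cell
  cl <- noise_chol(nc, truth$noise$rho)
  lapply(seq_len(design$n_subjects), function(s) {
    patterns <- subject_patterns(truth)
    data <- array(0, c(n_trial, nc, n_time))
    object_label <- integer(n_trial)
    mask_label <- character(n_trial)
    row <- 0L
    for (i in seq_len(nrow(cells))) {
      tmpl <- signal_template(truth, patterns, cells$object[i], cells$mask[i],
                              time_ms)
      for (k in seq_len(design$trials_per_cell)) {
        row <- row + 1L
        noise <- truth$noise$scale *
          crossprod(cl, matrix(stats::rnorm(nc * n_time), nc, n_time))
        data[row, , ] <- tmpl + noise
        object_label[row] <- cells$object[i]
        mask_label[row] <- cells$mask[i]
      }
    }
    epoch_set(data, object_label, mask_label, time_ms)
  })
}

#' Simulate an fMRI dataset with planted ROI geometry
#'
#' Generates run-wise voxel response patterns (betas) for each subject and
#' ROI, plus a small 3-D volume with an informative cube for searchlight
#' tests. Each ROI's noiseless condition patterns are built from the model
#' layers' feature matrices, mixed per mask condition with the weights in
#' `truth$roi_geometry` and projected to voxels, so the ROI's noiseless RDM
#' correlates most with the layer(s) carrying maximal weight.
#'
#' Betas are produced at presentation level: with the default design each run
#' contributes 24 objects x 2 masks x 2 presentations = 96 betas. Use
#' [average_presentations()] to collapse to one pattern per condition per run
#' before decoding.
#'
#' @param design A [design_spec()].
#' @param truth A [ground_truth()] (supplies `roi_geometry`).
#' @param model_rdms A [make_model_rdms()] result with matching `n_objects`
#'   and at least as many layers as the geometry references.
#' @param seed Integer seed.
#' @param n_voxels Voxels per ROI.
#' @param noise_scale Standard deviation of run/presentation noise relative
#'   to a unit-variance pattern.
#' @param volume_dim Dimensions of the searchlight test volume.
#' @param signal_cube Integer vector `c(x0, y0, z0, width)`: the corner and
#'   edge length of the cube of informative voxels planted in the volume.
#' @return A list (one element per subject) of lists with `rois` (per-ROI
#'   beta arrays, run x beta x voxel, with a `conditions` attribute
#'   data.frame), `volume` (run x beta x x x y x z array), `mask` (logical
#'   volume), and `conditions` (the beta-level condition table).
#' @export
simulate_fmri_dataset <- function(design, truth, model_rdms, seed = 1,
                                  n_voxels = 60, noise_scale = 0.6,
                                  volume_dim = c(9, 9, 9),
                                  signal_cube = c(2, 2, 2, 3)) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "ground_truth"),
            inherits(model_rdms, "model_rdm_set"))
  if (is.null(truth$roi_geometry) || !length(truth$roi_geometry))
    stop("ground_truth has no roi_geometry")
  if (truth$n_layers > model_rdms$n_layers)
    stop("roi_geometry references more layers than model_rdms provides")
  if (model_rdms$n_objects != design$n_objects)
    stop("model_rdms n_objects does not match the design")
  set.seed(seed)
  masks <- design$mask_conditions
  conds <- expand.grid(presentation = seq_len(design$presentations_per_run),
                       mask = masks,
                       object = seq_len(design$n_objects),
                       stringsAsFactors = FALSE)[, c("object", "mask", "presentation")]
  n_beta <- nrow(conds)
  d_feat <- ncol(model_rdms$features[[1]])

  roi_patterns <- function(weights_by_mask, n_vox) {
    proj <- matrix(stats::rnorm(d_feat * n_vox), d_feat, n_vox) / sqrt(d_feat)
    pats <- lapply(masks, function(m) {
      w <- weights_by_mask[[m]]
      feat <- Reduce(`+`, Map(function(wl, fl) sqrt(wl) * fl,
                              w, model_rdms$features[seq_along(w)]))
      p <- feat %*% proj                      # object x voxel
      p / stats::sd(p)
    })
    stats::setNames(pats, masks)
  }

  lapply(seq_len(design$n_subjects), function(s) {
    rois <- lapply(truth$roi_geometry, function(geom) {
      pats <- roi_patterns(geom, n_voxels)
      betas <- array(0, c(design$n_runs, n_beta, n_voxels))
      for (r in seq_len(design$n_runs)) for (b in seq_len(n_beta)) {
        betas[r, b, ] <- pats[[conds$mask[b]]][conds$object[b], ] +
          stats::rnorm(n_voxels, sd = noise_scale)
      }
      attr(betas, "conditions") <- conds
      betas
    })
    # Volume: informative patterns confined to one cube, noise elsewhere.
    nv <- prod(volume_dim)
    vol_flat <- array(stats::rnorm(design$n_runs * n_beta * nv, sd = noise_scale),
                      c(design$n_runs, n_beta, nv))
    cube_idx <- cube_voxels(volume_dim, signal_cube)
    deep <- model_rdms$features[[model_rdms$n_layers]]
    proj <- matrix(stats::rnorm(d_feat * length(cube_idx)), d_feat,
                   length(cube_idx)) / sqrt(d_feat)
    cube_pat <- deep %*% proj
    cube_pat <- cube_pat / stats::sd(cube_pat)
    for (r in seq_len(design$n_runs)) for (b in seq_len(n_beta)) {
      vol_flat[r, b, cube_idx] <- vol_flat[r, b, cube_idx] +
        cube_pat[conds$object[b], ]
    }
    list(rois = rois,
         volume = array(vol_flat, c(design$n_runs, n_beta, volume_dim)),
         mask = array(TRUE, volume_dim),
         conditions = conds,
         signal_cube = signal_cube)
  })
}

cube_voxels <- function(volume_dim, cube) {
  xs <- cube[1]:(cube[1] + cube[4] - 1)
  ys <- cube[2]:(cube[2] + cube[4] - 1)
  zs <- cube[3]:(cube[3] + cube[4] - 1)
  if (max(xs) > volume_dim[1] || max(ys) > volume_dim[2] || max(zs) > volume_dim[3])
    stop("signal cube exceeds the volume")
  idx <- expand.grid(x = xs, y = ys, z = zs)
  (idx$z - 1) * volume_dim[1] * volume_dim[2] + (idx$y - 1) * volume_dim[1] + idx$x
}

#' Collapse presentation-level betas to one pattern per condition and run
#'
#' @param betas A run x beta x voxel array with a `conditions` attribute, as
#'   produced by [simulate_fmri_dataset()].
#' @param mask Optional mask-condition label to select before averaging.
#' @return A run x condition x voxel array (conditions = objects, ordered),
#'   with an `objects` attribute.
#' @export
average_presentations <- function(betas, mask = NULL) {
  conds <- attr(betas, "conditions")
  if (is.null(conds)) stop("betas lack a conditions attribute")
  keep <- if (is.null(mask)) rep(TRUE, nrow(conds)) else conds$mask == mask
  if (!any(keep)) stop("no betas for mask condition: ", mask)
  sub <- conds[keep, , drop = FALSE]
  objects <- sort(unique(sub$object))
  out <- array(0, c(dim(betas)[1], length(objects), dim(betas)[3]))
  for (i in seq_along(objects)) {
    sel <- which(keep)[sub$object == objects[i]]
    out[, i, ] <- apply(betas[, sel, , drop = FALSE], c(1, 3), mean)
  }
  attr(out, "objects") <- objects
  out
}

#' Simulate voxel time series for HRF-selection testing
#'
#' Each voxel's series is the convolution of a shared event train with that
#' voxel's assigned haemodynamic response function from a parametric family,
#' plus white noise — a parameter-recovery fixture for
#' [fit_glm_hrf_select()].
#'
#' @param hrf_index_per_voxel Integer vector assigning each voxel a kernel
#'   index in `family`.
#' @param family An [hrf_family()].
#' @param n_conditions Number of event conditions.
#' @param events_per_condition Events per condition.
#' @param tr Repetition time in seconds.
#' @param n_scans Number of volumes.
#' @param amplitudes Per-condition response amplitudes.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @return A list with `series` (scan x voxel matrix), `events` (data.frame
#'   with onset, duration, condition — BIDS-style columns), `amplitudes`, and
#'   `hrf_index` (the generating assignment).
#' @export
simulate_fmri_timeseries <- function(hrf_index_per_voxel, family = hrf_family(),
                                     n_conditions = 4, events_per_condition = 8,
                                     tr = 2, n_scans = 160,
                                     amplitudes = rep(1, n_conditions),
                                     noise_sd = 0.1, seed = 1) {
  if (any(hrf_index_per_voxel < 1) || any(hrf_index_per_voxel > family$n_kernels))
    stop("hrf_index_per_voxel out of range for the HRF family")
  set.seed(seed)
  dur <- n_scans * tr
  n_ev <- n_conditions * events_per_condition
  onsets <- sort(stats::runif(n_ev, 0, dur - 20))
  events <- data.frame(onset = onsets, duration = 0.5,
                       condition = sample(rep(seq_len(n_conditions),
                                              events_per_condition)))
  n_vox <- length(hrf_index_per_voxel)
  series <- matrix(0, n_scans, n_vox)
  for (v in seq_len(n_vox)) {
    X <- design_matrix(events, family, hrf_index_per_voxel[v], tr, n_scans)
    series[, v] <- X %*% amplitudes + stats::rnorm(n_scans, sd = noise_sd)
  }
  list(series = series, events = events, amplitudes = amplitudes,
       hrf_index = hrf_index_per_voxel)
}
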