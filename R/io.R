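#' @title Containers, configuration, and pipeline orchestration
#' @description Plain-text dataset containers (a directory of TSV arrays
#'   plus JSON metadata, mirroring the logical group layout `/data`,
#'   `/labels/object`, `/labels/mask`, `/time_ms`, `/channels`), square-TSV
#'   RDM files, NIfTI export for volumetric maps, YAML run configuration,
#'   and the end-to-end [run_pipeline()] driver.
#' @name io
NULL

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !is.null(colnames(x)))
}

read_tsv_matrix <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, sep = "\t", header = header))
}

#' Write an epoch or TFR set to a plain-text container
#'
#' The container is a directory holding one file per logical group:
#' `meta.json` (type and dimensions), `data.tsv` (the array flattened to
#' rows of (trial, channel\[, frequency\]) by time columns; complex TFR
#' coefficients as paired `data_re.tsv`/`data_im.tsv`), `labels_object.tsv`,
#' `labels_mask.tsv`, `time_ms.tsv`, and `channels.tsv`. Everything is
#' inspectable without the package.
#'
#' @param dataset An [epoch_set()] or `tfr_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_container <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(dims = dim(if (inherits(dataset, "tfr_set")) dataset$coeffs
                          else dataset$data))
  if (inherits(dataset, "epoch_set")) {
    meta$type <- "epoch_set"
    d <- dim(dataset$data)
    flat <- matrix(aperm(dataset$data, c(3, 2, 1)), nrow = d[1] * d[2],
                   ncol = d[3], byrow = TRUE)
    write_tsv(flat, file.path(path, "data.tsv"))
  } else if (inherits(dataset, "tfr_set")) {
    meta$type <- "tfr_set"
    meta$freqs_hz <- dataset$freqs_hz
    d <- dim(dataset$coeffs)
    flat <- matrix(aperm(dataset$coeffs, c(4, 3, 2, 1)),
                   nrow = prod(d[1:3]), ncol = d[4], byrow = TRUE)
    write_tsv(Re(flat), file.path(path, "data_re.tsv"))
    write_tsv(Im(flat), file.path(path, "data_im.tsv"))
  } else stop("unsupported dataset class: ", class(dataset)[1])
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_tsv(matrix(dataset$object_label), file.path(path, "labels_object.tsv"))
  write_tsv(matrix(dataset$mask_label), file.path(path, "labels_mask.tsv"))
  write_tsv(matrix(dataset$time_ms), file.path(path, "time_ms.tsv"))
  write_tsv(matrix(dataset$channel_ids), file.path(path, "channels.tsv"))
  invisible(path)
}

container_file <- function(path, file, group) {
  f <- file.path(path, file)
  if (!file.exists(f))
    stop("malformed container at ", path, ": missing group ", group)
  f
}

#' Read a dataset back from a plain-text container
#' @param path Directory written by [write_container()].
#' @return The reconstructed `epoch_set` or `tfr_set`.
#' @export
read_container <- function(path) {
  meta <- jsonlite::read_json(container_file(path, "meta.json", "/meta"),
                              simplifyVector = TRUE)
  object_label <- drop(read_tsv_matrix(
    container_file(path, "labels_object.tsv", "/labels/object")))
  mask_label <- as.character(drop(read_tsv_matrix(
    container_file(path, "labels_mask.tsv", "/labels/mask"))))
  time_ms <- drop(read_tsv_matrix(container_file(path, "time_ms.tsv", "/time_ms")))
  channels <- as.character(drop(read_tsv_matrix(
    container_file(path, "channels.tsv", "/channels"))))
  dims <- meta$dims
  if (meta$type == "epoch_set") {
    flat <- read_tsv_matrix(container_file(path, "data.tsv", "/data"))
    data <- aperm(array(t(flat), dims[c(3, 2, 1)]), c(3, 2, 1))
    epoch_set(data, object_label, mask_label, time_ms, channels)
  } else if (meta$type == "tfr_set") {
    re <- read_tsv_matrix(container_file(path, "data_re.tsv", "/data (re)"))
    im <- read_tsv_matrix(container_file(path, "data_im.tsv", "/data (im)"))
    coeffs <- aperm(array(t(re + 1i * im), dims[c(4, 3, 2, 1)]), c(4, 3, 2, 1))
    structure(list(coeffs = coeffs, freqs_hz = meta$freqs_hz,
                   time_ms = time_ms, object_label = object_label,
                   mask_label = mask_label, channel_ids = channels),
              class = "tfr_set")
  } else stop("malformed container at ", path, ": unknown type ", meta$type)
}

#' Write / read an RDM as a square TSV with a condition-id header
#' @param rdm Square matrix (RDM or accuracy matrix).
#' @param path Output file.
#' @export
write_rdm_tsv <- function(rdm, path) {
  m <- as.matrix(rdm)
  colnames(m) <- if (is.null(colnames(m))) paste0("c", seq_len(ncol(m)))
  else colnames(m)
  write_tsv(m, path)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @return `read_rdm_tsv` returns an `rdm`.
#' @export
read_rdm_tsv <- function(path) {
  m <- read_tsv_matrix(path, header = TRUE)
  as_rdm(m)
}

#' Export a searchlight map (or any 3-D array) as NIfTI-1
#' @param map A `searchlight_map` or 3-D numeric array.
#' @param path Output `.nii` path.
#' @export
write_map_nifti <- function(map, path) {
  arr <- if (inherits(map, "searchlight_map")) map$values else map
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Fills in defaults for any missing block: the design defaults to the full
#' reference layout, stage parameters default to the reference analysis
#' values (4 pseudo-trial bins, 100 repetitions, 10,000 permutations,
#' cluster definition threshold 0.005, cluster threshold 0.05, searchlight
#' radius 4), and all stages are enabled.
#'
#' @param path YAML file; `NULL` returns the pure defaults.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    seed = 1,
    design = list(),
    truth = list(),
    stages = c("simulate", "preprocess", "decode", "rsa", "stats"),
    params = list(n_reps = 100, n_bins = 4, n_perm = 10000, cdt = 0.005,
                  alpha = 0.05, radius = 4, n_boot = 1000, n_layers = 8)
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$params)) {
    if (is.null(cfg$params[[nm]])) cfg$params[[nm]] <- defaults$params[[nm]]
  }
  known <- c("simulate", "preprocess", "decode", "rsa", "stats")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("unknown stage(s) in config: ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

# Per-stage seed substreams derived from the single config seed.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, preprocess = 2L, decode = 3L, rsa = 4L,
            stats = 5L, tfr = 6L, select = 7L)
  (as.integer(seed) * 97L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes simulate -> preprocess -> decode -> rsa -> stats according to
#' the config's stage toggles, writing TSV results and a JSON manifest
#' (seed, package version, parameter echo) to `out_dir`. All randomness
#' flows from the single config seed through named per-stage substreams, so
#' the same config and seed reproduce identical outputs.
#'
#' @param config A `run_config` from [read_run_config()], or `NULL` for
#'   defaults.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("pipeline")) {
  if (is.null(config)) config <- read_run_config(NULL)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  design <- do.call(design_spec, config$design)
  truth <- do.call(ground_truth,
                   c(list(design = design), config$truth,
                     list(seed = stage_seed(config$seed, "simulate"))))
  p <- config$params
  run_stage("simulate", {
    res$eeg <- simulate_eeg_dataset(design, truth,
                                     seed = stage_seed(config$seed, "simulate"))
  })
  run_stage("preprocess", {
    res$eeg <- lapply(res$eeg, function(e) mnn_whiten(baseline_correct(e)))
  })
  run_stage("decode", {
    seeds <- stage_seed(config$seed, "decode") + seq_along(res$eeg)
    res$decoding <- lapply(seq_along(res$eeg), function(s) {
      list(early = decode_timecourse(res$eeg[[s]], "within-early",
                                     n_reps = p$n_reps, n_bins = p$n_bins,
                                     seed = seeds[s]),
           late = decode_timecourse(res$eeg[[s]], "within-late",
                                    n_reps = p$n_reps, n_bins = p$n_bins,
                                    seed = seeds[s] + 1L))
    })
    tc <- sapply(res$decoding, function(d) d$early$timecourse)
    out <- data.frame(time_ms = design$time_ms,
                      early = rowMeans(tc),
                      late = rowMeans(sapply(res$decoding,
                                             function(d) d$late$timecourse)))
    write_tsv(out, file.path(out_dir, "decoding_timecourse.tsv"))
  })
  run_stage("rsa", {
    model <- make_model_rdms(p$n_layers, n_objects = design$n_objects,
                             seed = stage_seed(config$seed, "rsa"))
    res$rsa <- lapply(res$decoding, function(d) rsa_timecourse(d$early, model))
    ceil <- noise_ceiling(lapply(res$decoding, function(d) {
      # subject RDM at the peak decoding time point
      d$early$acc[, , which.max(d$early$timecourse)]
    }))
    res$noise_ceiling <- ceil
    write_tsv(data.frame(bound = c("lower", "upper"),
                         value = c(ceil$lower, ceil$upper)),
              file.path(out_dir, "noise_ceiling.tsv"))
  })
  run_stage("stats", {
    maps <- t(sapply(res$decoding, function(d) d$early$timecourse - 50))
    res$stats <- cluster_inference(maps, dims = ncol(maps), cdt = p$cdt,
                                    alpha = p$alpha,
                                    n_perm = min(p$n_perm, 2000),
                                    seed = stage_seed(config$seed, "stats"))
    write_tsv(data.frame(time_ms = design$time_ms,
                         p = as.numeric(res$stats$p_map),
                         cluster_id = as.integer(res$stats$cluster_id),
                         significant = as.logical(res$stats$sig_mask)),
              file.path(out_dir, "cluster_stats.tsv"))
  })
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("maskmvpa")),
                   stages = config$stages,
                   params = config$params,
                   design = list(n_objects = design$n_objects,
                                 trials_per_cell = design$trials_per_cell,
                                 n_channels = design$n_channels,
                                 n_subjects = design$n_subjects))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
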