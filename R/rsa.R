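#' Representational dissimilarity matrix from a feature matrix
#'
#' Dissimilarity between every pair of items is 1 - Pearson correlation of
#' their feature vectors (the convention for model layers). The diagonal is
#' undefined (NA).
#'
#' @param features item x dimension numeric matrix (>= 2 dimensions).
#' @return A K x K matrix of class `rdm`, entries in `[0, 2]`.
#' @examples
#' f <- matrix(rnorm(12), 3, 4)
#' rdm_from_features(f)
#' @export
rdm_from_features <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need >= 2 feature dimensions")
  sds <- apply(features, 1, stats::sd)
  if (any(sds == 0))
    stop("constant feature vector(s) for item(s) ",
         paste(which(sds == 0), collapse = ", "),
         ": correlation dissimilarity undefined")
  d <- 1 - stats::cor(t(features))
  diag(d) <- NA
  structure(d, class = c("rdm", "matrix"))
}

#' Construct an RDM from a square dissimilarity matrix
#' @param values Symmetric K x K numeric matrix; the diagonal is ignored.
#' @return Object of class `rdm`.
#' @export
as_rdm <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  diag(values) <- NA
  if (!isTRUE(all.equal(unname(values), unname(t(values)))))
    stop("RDM must be symmetric")
  structure(values, class = c("rdm", "matrix"))
}

# Lower-triangle vectorization (diagonal excluded); accepts rdm/accuracy
# matrices or pre-vectorized numeric input.
lower_tri_vec <- function(x) {
  if (is.matrix(x)) x[lower.tri(x)] else as.numeric(x)
}

#' Correlate two RDMs
#'
#' Vectorizes the lower triangles (diagonal excluded) and computes their
#' rank (Spearman, default) or Pearson correlation. Decoding accuracy
#' matrices are valid inputs — they serve as neural RDMs.
#'
#' @param a,b RDMs (or accuracy matrices) of the same K.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation in `[-1, 1]`.
#' @export
rdm_correlate <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.matrix(a) && is.matrix(b) && !all(dim(a) == dim(b)))
    stop("RDMs must have the same number of conditions")
  va <- lower_tri_vec(a); vb <- lower_tri_vec(b)
  if (length(va) != length(vb)) stop("RDMs must have the same number of pairs")
  if (length(va) < 6) warning("fewer than 4 conditions: rank correlation is unstable")
  stats::cor(va, vb, method = method)
}

#' Noise ceiling for RDM correlations
#'
#' Bounds on the maximal RDM correlation attainable given inter-subject
#' variability: the lower bound correlates each subject's RDM with the mean
#' RDM of all other subjects; the upper bound correlates it with the mean
#' of all subjects (including itself). Both are averaged over subjects.
#'
#' @param subject_rdms List of >= 3 same-sized RDMs (or accuracy matrices).
#' @param method Correlation flavor passed to [rdm_correlate()].
#' @return Object of class `ceiling_pair` with `lower` and `upper`.
#' @export
noise_ceiling <- function(subject_rdms, method = "spearman") {
  n <- length(subject_rdms)
  if (n < 3) stop("noise ceiling needs >= 3 subjects")
  vecs <- sapply(subject_rdms, lower_tri_vec)   # pair x subject
  grand <- rowMeans(vecs)
  lower <- mean(sapply(seq_len(n), function(s)
    stats::cor(vecs[, s], rowMeans(vecs[, -s, drop = FALSE]), method = method)))
  upper <- mean(sapply(seq_len(n), function(s)
    stats::cor(vecs[, s], grand, method = method)))
  structure(list(lower = lower, upper = upper), class = "ceiling_pair")
}

#' @export
print.ceiling_pair <- function(x, ...) {
  cat("Noise ceiling: [", round(x$lower, 3), ",", round(x$upper, 3), "]\n")
  invisible(x)
}

#' Commonality analysis for two predictor RDMs
#'
#' Partitions the variance of a target RDM explained by two predictor RDMs
#' into shared and unique components, on rank-transformed lower-triangle
#' vectors (consistent with Spearman-based RSA):
#' `C = R2(target ~ a) + R2(target ~ b) - R2(target ~ a + b)`.
#' `C` can be negative (suppression); it is bounded above by each pairwise
#' R2. The identity `C + unique_a + unique_b = R2_full` holds exactly.
#'
#' @param target,predictor_a,predictor_b RDMs (or accuracy matrices /
#'   pre-vectorized pair vectors) over the same conditions.
#' @param rank_transform Rank-transform the vectors first (default TRUE).
#' @return Object of class `commonality_result`: `shared`, `unique_a`,
#'   `unique_b`, `r2_a`, `r2_b`, `r2_full`.
#' @export
commonality <- function(target, predictor_a, predictor_b,
                        rank_transform = TRUE) {
  t_v <- lower_tri_vec(target)
  a_v <- lower_tri_vec(predictor_a)
  b_v <- lower_tri_vec(predictor_b)
  if (length(unique(c(length(t_v), length(a_v), length(b_v)))) != 1)
    stop("RDMs must share the same condition set")
  if (rank_transform) {
    t_v <- rank(t_v); a_v <- rank(a_v); b_v <- rank(b_v)
  }
  r_ta <- stats::cor(t_v, a_v)
  r_tb <- stats::cor(t_v, b_v)
  r_ab <- stats::cor(a_v, b_v)
  if (abs(r_ab) > 0.999)
    warning("predictor RDMs are (near-)collinear; commonality is unstable")
  r2_a <- r_ta^2
  r2_b <- r_tb^2
  r2_full <- if (abs(r_ab) < 1) {
    (r_ta^2 + r_tb^2 - 2 * r_ta * r_tb * r_ab) / (1 - r_ab^2)
  } else r2_a
  shared <- r2_a + r2_b - r2_full
  structure(list(shared = shared,
                 unique_a = r2_full - r2_b,
                 unique_b = r2_full - r2_a,
                 r2_a = r2_a, r2_b = r2_b, r2_full = r2_full),
            class = "commonality_result")
}

#' @export
print.commonality_result <- function(x, ...) {
  cat("Commonality: shared =", signif(x$shared, 4),
      "| unique_a =", signif(x$unique_a, 4),
      "| unique_b =", signif(x$unique_b, 4),
      "| R2_full =", signif(x$r2_full, 4), "\n")
  invisible(x)
}

#' Layer-wise RSA of a decoding timecourse
#'
#' Correlates the neural RDM (pairwise accuracy matrix) at each time point
#' with each model layer's RDM, yielding a layer x time matrix of Spearman
#' correlations — the per-subject input to group-level inference.
#'
#' @param timecourse A [decode_timecourse()] result.
#' @param model_rdms A [make_model_rdms()] result.
#' @return Matrix layer x time of correlations.
#' @export
rsa_timecourse <- function(timecourse, model_rdms) {
  stopifnot(inherits(timecourse, "decoding_timecourse"),
            inherits(model_rdms, "model_rdm_set"))
  n_time <- length(timecourse$time_ms)
  out <- matrix(0, model_rdms$n_layers, n_time)
  for (l in seq_len(model_rdms$n_layers)) {
    for (t in seq_len(n_time)) {
      out[l, t] <- rdm_correlate(timecourse$acc[, , t], model_rdms$rdms[[l]])
    }
  }
  rownames(out) <- paste0("layer", seq_len(model_rdms$n_layers))
  out
}
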