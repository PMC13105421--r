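# The d-test: weighted divergence from the normal reference, calibrated to
# [0, 1], banded into normal / benign / malignant; per-patch posteriors from
# the exponential likelihoods; SEM+AFM fusion.

WD_BAND_EDGES <- c(0.4, 0.6)
WD_CAL_ANCHORS <- c(0.2, 0.5, 0.8)

# smoothed-one-hot matrix: column b is the distribution assigned to a test
# value falling in bin b (same kernel and floor as training distributions)
onehot_matrix <- function(n_bins, bandwidth) {
  S <- smoothing_matrix(n_bins, bandwidth)
  apply(diag(n_bins), 2, smooth_counts, S = S)
}

# raw weighted divergence of test patches from the normal reference.
# fm_attrs: n_patch x n_attr matrix of attribute values.
raw_scores <- function(fm_attrs, reference, weights, jsd_variant = "standard") {
  attrs <- reference$attributes
  n_bins <- reference$n_bins
  OH <- onehot_matrix(n_bins, reference$bandwidth)
  Qn <- reference$dist$normal
  W <- weights$weights[attrs]
  # suppress per-value clipping warnings: held-out values may exceed the
  # training range by design; they land in the end bins
  idx <- suppressWarnings(vapply(seq_along(attrs), function(i)
    bin_index(fm_attrs[, i], reference$bin_edges[[attrs[i]]]),
    integer(nrow(fm_attrs))))
  idx <- matrix(idx, nrow = nrow(fm_attrs))
  vapply(seq_len(nrow(fm_attrs)), function(j) {
    Pt <- OH[, idx[j, ], drop = FALSE]
    dv <- divergence_cols(weights$divergence_kind, Pt, Qn, jsd_variant)
    sum(W * dv)
  }, numeric(1))
}

#' Fit the d-score calibration for one divergence
#'
#' A monotone piecewise-linear map from raw weighted divergence to the
#' `[0, 1]` d scale, anchored so the median raw score of training-normal
#' patches maps to 0.2, training-benign to 0.5 and training-malignant to
#' 0.8; extended linearly beyond the outer anchors and clipped to `[0, 1]`.
#' This anchoring is what makes the fixed decision bands (0.4, 0.6)
#' meaningful on any dataset. Non-increasing anchor sequences (no class
#' separation) are made weakly increasing before fitting.
#'
#' @param raw Numeric vector of raw training scores.
#' @param labels Class label of each score.
#' @return A `calibration_map`.
#' @export
fit_calibration <- function(raw, labels) {
  med <- vapply(wd_classes, function(cls) median(raw[labels == cls]),
                numeric(1))
  med <- cummax(med)
  eps <- 1e-9 * max(1, abs(med[3] - med[1]))
  med <- med + eps * (0:2)         # guarantee strict monotonicity
  structure(list(raw_anchors = med, d_anchors = WD_CAL_ANCHORS),
            class = "calibration_map")
}

#' Apply a calibration map
#'
#' @param calibration A `calibration_map` from [fit_calibration()].
#' @param raw Raw score(s).
#' @return d score(s) in `[0, 1]`.
#' @export
apply_calibration <- function(calibration, raw) {
  x <- calibration$raw_anchors; y <- calibration$d_anchors
  s1 <- (y[2] - y[1]) / (x[2] - x[1])
  s2 <- (y[3] - y[2]) / (x[3] - x[2])
  d <- ifelse(raw < x[2],
              y[2] + (raw - x[2]) * s1,
              y[2] + (raw - x[2]) * s2)
  as.vector(pmin(pmax(d, 0), 1))
}

#' Band assignment of a d score
#'
#' Normal for `d` in `[0, 0.4)`, benign in `[0.4, 0.6)`, malignant in
#' `[0.6, 1]` (half-open bands; the shared boundary values 0.4 and 0.6
#' belong to the upper band).
#'
#' @param d d score(s) in `[0, 1]`.
#' @return Character vector of class labels.
#' @export
classify_bands <- function(d) {
  if (any(!is.finite(d)) || any(d < -1e-9) || any(d > 1 + 1e-9))
    stop("d scores must lie in [0, 1]", call. = FALSE)
  ifelse(d < WD_BAND_EDGES[1], "normal",
         ifelse(d < WD_BAND_EDGES[2], "benign", "malignant"))
}

#' Consensus over the three divergence scores
#'
#' Policy `"median"`: the consensus d is the median of the three scores and
#' the label its band. Policy `"per_divergence"`: each divergence keeps its
#' own band assignment (the consensus d is still reported as the median, for
#' ranking).
#'
#' @param d Named numeric vector of d scores (one per divergence).
#' @param policy `"median"` or `"per_divergence"`.
#' @return List with `d` (consensus scalar), `label` (single label for
#'   `"median"`; named per-divergence labels for `"per_divergence"`).
#' @export
consensus <- function(d, policy = c("median", "per_divergence")) {
  policy <- match.arg(policy)
  dm <- unname(median(d))
  if (policy == "median") list(d = dm, label = classify_bands(dm))
  else list(d = dm, label = vapply(d, classify_bands, character(1)))
}

#' Class posteriors from the exponential likelihood models
#'
#' Softmax (equal class priors) of the three class log-likelihoods from
#' [class_likelihood()], computed stably by subtracting the maximum.
#'
#' @param features Named feature vector.
#' @param reference A trained `class_reference`.
#' @return Named vector `c(normal=, benign=, malignant=)` summing to 1.
#' @export
posteriors <- function(features, reference) {
  ll <- vapply(wd_classes, function(cls)
    class_likelihood(features, reference, cls), numeric(1))
  e <- exp(ll - max(ll))
  e / sum(e)
}

#' d-test of a single feature vector
#'
#' Represents each test attribute as a smoothed point mass on the
#' attribute's shared bins (same kernel and floor as training), scores the
#' weighted divergence from the *normal* class reference (so normal patches
#' score low, malignant high), and maps the raw score through the trained
#' calibration.
#'
#' @param features Named feature vector ([extract_features()]).
#' @param reference A trained `class_reference`.
#' @param weights A `weight_vector` or named list of them (one per
#'   divergence kind).
#' @param calibration A `calibration_map` or named list keyed like
#'   `weights`.
#' @param jsd_variant Passed through to the JSD.
#' @return Named numeric vector of d scores, one per divergence kind.
#' @export
d_test <- function(features, reference, weights, calibration,
                   jsd_variant = "standard") {
  if (inherits(weights, "weight_vector")) {
    weights <- setNames(list(weights), weights$divergence_kind)
    calibration <- setNames(list(calibration), names(weights))
  }
  x <- matrix(as.numeric(features[reference$attributes]), nrow = 1)
  vapply(names(weights), function(k) {
    raw <- raw_scores(x, reference, weights[[k]], jsd_variant)
    apply_calibration(calibration[[k]], raw)
  }, numeric(1))
}

#' Classify a feature matrix with a trained model
#'
#' Computes, per patch: d scores for all three divergences, band assignments
#' per divergence, the consensus assignment, and likelihood posteriors.
#'
#' @param fm Feature matrix of the patches to classify.
#' @param model A model from [train_model()].
#' @return Data frame with columns `source_id, patch_index, modality, label,
#'   d_JSD, d_HD, d_TD, P_Cn, P_Cb, P_Cm, assigned_JSD, assigned_HD,
#'   assigned_TD, assigned_consensus`.
#' @export
classify_dataset <- function(fm, model) {
  out <- lapply(intersect(wd_modalities, unique(fm$modality)),
                function(mod) {
    sub <- fm[fm$modality == mod, , drop = FALSE]
    mm <- model$modalities[[mod]]
    if (is.null(mm)) stop("model has no reference for modality ", mod,
                          call. = FALSE)
    ref <- mm$reference
    xs <- as.matrix(sub[, ref$attributes, drop = FALSE])
    d <- vapply(wd_divergences, function(k)
      apply_calibration(mm$calibration[[k]],
                        raw_scores(xs, ref, mm$weights[[k]],
                                   model$config$jsd_variant)),
      numeric(nrow(sub)))
    d <- matrix(d, nrow = nrow(sub),
                dimnames = list(NULL, wd_divergences))
    post <- t(apply(xs, 1, function(r)
      posteriors(setNames(r, ref$attributes), ref)))
    cons <- classify_bands(apply(d, 1, median))
    data.frame(
      source_id = sub$source_id, patch_index = sub$patch_index,
      modality = sub$modality, label = sub$label,
      d_JSD = d[, "JSD"], d_HD = d[, "HD"], d_TD = d[, "TD"],
      P_Cn = post[, "normal"], P_Cb = post[, "benign"],
      P_Cm = post[, "malignant"],
      assigned_JSD = classify_bands(d[, "JSD"]),
      assigned_HD = classify_bands(d[, "HD"]),
      assigned_TD = classify_bands(d[, "TD"]),
      assigned_consensus = cons,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fuse the SEM and AFM results of one subject
#'
#' Fused d per divergence is the mean of the two modality d scores; fused
#' posteriors are the renormalized element-wise product of the two posterior
#' vectors (independent-modality likelihood combination); the fused label is
#' the band of the consensus (median) fused d.
#'
#' @param sem,afm `d_test_result` lists (fields `d`, `posteriors`,
#'   `modality`, `source_id`, `patch_index`) — one SEM, one AFM, same
#'   subject.
#' @return A fused `d_test_result` with `modality = "fused"`.
#' @export
fuse_modalities <- function(sem, afm) {
  if (identical(sem$modality, afm$modality))
    stop("fusion needs one SEM and one AFM result, got two ",
         sem$modality, call. = FALSE)
  d <- (sem$d + afm$d) / 2
  p <- sem$posteriors * afm$posteriors
  p <- p / sum(p)
  structure(list(
    d = d, posteriors = p,
    assigned = consensus(d, "median")$label,
    modality = "fused", source_id = sem$source_id,
    patch_index = sem$patch_index),
    class = "d_test_result")
}

#' Fuse per-modality classification tables
#'
#' Pairs SEM and AFM rows of [classify_dataset()] output on
#' `(source_id, patch_index)` and applies [fuse_modalities()] rowwise.
#'
#' @param results Classification data frame containing both modalities.
#' @return Data frame in the same layout with `modality = "fused"`.
#' @export
fuse_results <- function(results) {
  sem <- results[results$modality == "SEM", , drop = FALSE]
  afm <- results[results$modality == "AFM", , drop = FALSE]
  key <- function(x) paste(x$source_id, x$patch_index)
  common <- intersect(key(sem), key(afm))
  if (!length(common)) stop("no SEM/AFM pairs to fuse", call. = FALSE)
  sem <- sem[match(common, key(sem)), ]
  afm <- afm[match(common, key(afm)), ]
  d <- (as.matrix(sem[, c("d_JSD", "d_HD", "d_TD")]) +
        as.matrix(afm[, c("d_JSD", "d_HD", "d_TD")])) / 2
  post <- as.matrix(sem[, c("P_Cn", "P_Cb", "P_Cm")]) *
    as.matrix(afm[, c("P_Cn", "P_Cb", "P_Cm")])
  post <- post / rowSums(post)
  cons <- classify_bands(apply(d, 1, median))
  data.frame(
    source_id = sem$source_id, patch_index = sem$patch_index,
    modality = "fused", label = sem$label,
    d_JSD = d[, 1], d_HD = d[, 2], d_TD = d[, 3],
    P_Cn = post[, 1], P_Cb = post[, 2], P_Cm = post[, 3],
    assigned_JSD = classify_bands(d[, 1]),
    assigned_HD = classify_bands(d[, 2]),
    assigned_TD = classify_bands(d[, 3]),
    assigned_consensus = cons,
    stringsAsFactors = FALSE)
}
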