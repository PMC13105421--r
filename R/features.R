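# Per-subband statistical features of the wavelet decomposition.

wd_stats <- c("energy", "entropy", "mean", "std", "skewness", "kurtosis",
              "NE")

#' Canonical attribute names
#'
#' The fixed attribute order used by feature vectors, weight vectors and
#' model files: for each subband in the order `CA<levels>, CH1..CH<levels>,
#' CV1.., CD1..`, the seven statistics `energy, entropy, mean, std,
#' skewness, kurtosis, NE`, named `<stat>_<band>` (e.g. `NE_CH3`,
#' `energy_CA4`). With 4 levels: 13 subbands x 7 statistics = 91 attributes.
#'
#' @param levels Decomposition depth (default 4).
#' @return Character vector of attribute names.
#' @export
attribute_names <- function(levels = 4) {
  as.vector(vapply(subband_names(levels),
                   function(b) paste0(wd_stats, "_", b),
                   character(length(wd_stats))))
}

#' Normalized energy of a subband
#'
#' The fraction of the patch's total energy carried by one subband:
#' `sum(C^2) / sum(I^2)` with `C` the subband coefficients and `I` the patch
#' intensities. Under an orthogonal transform the normalized energies of the
#' 13 subbands sum to 1, which makes the feature robust to overall
#' illumination scaling.
#'
#' @param band Coefficient matrix of one subband.
#' @param patch An [image_patch] or intensity matrix.
#' @return Scalar in `[0, 1]` (0 with a warning for an all-zero patch).
#' @export
normalized_energy <- function(band, patch) {
  I <- if (inherits(patch, "image_patch")) patch$pixels else patch
  tot <- sum(I^2)
  if (tot == 0) {
    warning("all-zero patch: normalized energy defined as 0", call. = FALSE)
    return(0)
  }
  sum(band^2) / tot
}

# seven statistics of one coefficient matrix; zero-variance convention:
# skewness = kurtosis = entropy = 0. Moments are population moments
# (divisor n); kurtosis is the raw standardized 4th moment (Gaussian -> 3),
# not excess. Entropy is Shannon entropy in bits of the `bins`-bin histogram
# over the band's own range.
band_stats <- function(C, total_energy, entropy_bins = 64) {
  v <- as.vector(C)
  n <- length(v)
  m <- mean(v)
  s2 <- sum((v - m)^2) / n
  s <- sqrt(s2)
  # bands that are flat up to floating-point noise (std below 1e-12 on the
  # [0, 1] intensity scale) use the degenerate conventions
  if (s > 1e-12) {
    z <- (v - m) / s
    skw <- sum(z^3) / n
    krt <- sum(z^4) / n
    idx <- pmin(floor((v - min(v)) / (max(v) - min(v)) * entropy_bins),
                entropy_bins - 1)
    p <- tabulate(idx + 1L, nbins = entropy_bins) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  } else {
    skw <- 0; krt <- 0; ent <- 0
  }
  ne <- if (total_energy > 0) sum(v^2) / total_energy else 0
  c(energy = sum(v^2), entropy = ent, mean = m, std = s, skewness = skw,
    kurtosis = krt, NE = ne)
}

#' Extract the per-subband feature vector of a patch
#'
#' Computes, for each retained subband, energy, Shannon entropy (bits, of a
#' 64-bin histogram over the band's own range), mean, population standard
#' deviation, skewness, kurtosis (raw standardized 4th moment) and
#' normalized energy. Zero-variance bands get skewness, kurtosis and entropy
#' 0 by convention.
#'
#' @param subbands A `subband_set` from [dwt_decompose()].
#' @param patch The [image_patch] the subbands were derived from (needed for
#'   normalized energy).
#' @param entropy_bins Histogram bins for the entropy statistic.
#' @return Named numeric vector in the [attribute_names()] order, with
#'   attributes `modality`, `label`, `source_id`, `patch_index`.
#' @export
extract_features <- function(subbands, patch, entropy_bins = 64) {
  stopifnot(inherits(subbands, "subband_set"))
  I <- if (inherits(patch, "image_patch")) patch$pixels else patch
  tot <- sum(I^2)
  bands <- subband_names(subbands$levels)
  vals <- lapply(bands, function(b)
    band_stats(subbands$coefficients[[b]], tot, entropy_bins))
  out <- unlist(vals, use.names = FALSE)
  names(out) <- attribute_names(subbands$levels)
  if (inherits(patch, "image_patch")) {
    attr(out, "modality") <- patch$modality
    attr(out, "label") <- patch$label
    attr(out, "source_id") <- patch$source_id
    attr(out, "patch_index") <- patch$patch_index
  }
  out
}

#' Feature matrix of a patch collection
#'
#' Runs [dwt_decompose()] and [extract_features()] over a list of patches
#' and assembles one row per patch: metadata columns `source_id,
#' patch_index, modality, label` followed by the 91 attribute columns.
#'
#' @param patches List of [image_patch].
#' @param wavelet_name,levels,entropy_bins Passed through.
#' @return A `data.frame`.
#' @export
extract_feature_matrix <- function(patches, wavelet_name = "db4",
                                   levels = 4, entropy_bins = 64) {
  stopifnot(length(patches) > 0)
  feats <- t(vapply(patches, function(p)
    extract_features(dwt_decompose(p, wavelet_name, levels), p,
                     entropy_bins),
    numeric(7L * (3L * levels + 1L))))
  meta <- data.frame(
    source_id = vapply(patches, function(p) p$source_id, character(1)),
    patch_index = vapply(patches, function(p) p$patch_index, integer(1)),
    modality = vapply(patches, function(p) p$modality, character(1)),
    label = vapply(patches, function(p) p$label, character(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}

# attribute columns of a feature matrix
feature_columns <- function(fm) {
  setdiff(colnames(fm), c("source_id", "patch_index", "modality", "label"))
}
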