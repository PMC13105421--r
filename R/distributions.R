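# Per-attribute class distributions (kernel-smoothed histograms on shared
# bin edges) and exponential likelihood models.
#
# All three class distributions of an attribute live on identical bin edges
# so that divergences between them are defined; a probability floor after
# smoothing keeps every divergence finite.

WD_PROB_FLOOR <- 1e-9

#' Shared bin edges for an attribute
#'
#' Edges cover the pooled range of the supplied values (all classes, both
#' modalities) extended by a 5% margin on each side, so that held-out values
#' rarely fall outside. A degenerate (constant) attribute gets a tiny
#' symmetric range.
#'
#' @param values Pooled attribute values.
#' @param n_bins Number of bins (default 64).
#' @return Strictly increasing numeric vector of length `n_bins + 1`.
#' @export
make_bin_edges <- function(values, n_bins = 64) {
  lo <- min(values); hi <- max(values)
  r <- hi - lo
  if (r <= 0) r <- max(abs(lo), 1) * 1e-6
  seq(lo - 0.05 * r, hi + 0.05 * r, length.out = n_bins + 1)
}

# discrete Gaussian smoothing matrix in bin space with reflecting
# boundaries: mass leaving an edge folds back in, so the matrix is doubly
# stochastic — total mass is conserved and a uniform histogram stays
# uniform (no edge attenuation)
smoothing_matrix <- function(n_bins, bandwidth) {
  if (bandwidth <= 0) return(diag(n_bins))
  Tmax <- ceiling(6 * bandwidth)
  w <- dnorm(-Tmax:Tmax, sd = bandwidth)
  S <- matrix(0, n_bins, n_bins)
  for (j in seq_len(n_bins)) {
    for (t in seq_along(w)) {
      i <- j + t - Tmax - 1L
      while (i < 1L || i > n_bins) {     # reflect about the boundaries
        if (i < 1L) i <- 1L - i
        if (i > n_bins) i <- 2L * n_bins + 1L - i
      }
      S[i, j] <- S[i, j] + w[t]
    }
  }
  sweep(S, 2, colSums(S), "/")
}

# counts -> smoothed, floored, renormalized probability vector; the floor
# is applied slightly above WD_PROB_FLOOR so that every probability still
# exceeds the floor after the final renormalization
smooth_counts <- function(counts, S) {
  p <- as.vector(S %*% counts)
  p <- p / sum(p)
  p <- pmax(p, 1.01 * WD_PROB_FLOOR)
  p / sum(p)
}

# bin index of each value on the shared edges; out-of-range values are
# clipped into the end bins with a warning
bin_index <- function(values, bin_edges) {
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  if (any(idx < 1L | idx > n_bins)) {
    warning(sprintf("%d value(s) outside bin range clipped into end bins",
                    sum(idx < 1L | idx > n_bins)), call. = FALSE)
    idx <- pmin(pmax(idx, 1L), n_bins)
  }
  idx
}

#' Estimate a discretized attribute distribution
#'
#' Histograms the values on shared bin edges, convolves with a discrete
#' Gaussian kernel of standard deviation `bandwidth` (in bins), floors every
#' bin at 1e-9 and renormalizes to sum 1.
#'
#' @param values Attribute values (at least 1; training uses >= 2).
#' @param bin_edges Shared edges from [make_bin_edges()].
#' @param bandwidth Kernel standard deviation in bins (default 1; 0 disables
#'   smoothing).
#' @return A `feature_distribution`: list with `bin_edges`, `probabilities`,
#'   `smoothing_bandwidth`.
#' @export
estimate_distribution <- function(values, bin_edges, bandwidth = 1.0) {
  if (length(values) < 1) stop("no values to estimate from", call. = FALSE)
  n_bins <- length(bin_edges) - 1L
  counts <- tabulate(bin_index(values, bin_edges), nbins = n_bins)
  p <- smooth_counts(counts, smoothing_matrix(n_bins, bandwidth))
  structure(list(bin_edges = bin_edges, probabilities = p,
                 smoothing_bandwidth = bandwidth),
            class = "feature_distribution")
}

#' Maximum-likelihood exponential rate
#'
#' Closed-form MLE for already-shifted positive values: `lambda = 1 /
#' mean(x)`. Shifting (subtracting the pooled training minimum, plus a small
#' delta) happens in [train_reference()], because raw attributes such as
#' skewness can be negative while the exponential support is positive.
#'
#' @param values Positive (shifted) attribute values.
#' @return Rate `lambda > 0`.
#' @export
fit_exponential <- function(values) {
  if (length(values) < 1) stop("no values to fit", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("non-positive mean after shift; cannot fit exponential rate",
         call. = FALSE)
  1 / m
}

# shift a test/train value onto the positive exponential support
shift_values <- function(x, shift_min, delta) {
  pmax(x - shift_min, 0) + delta
}

#' Per-class stage ranges of each attribute
#'
#' For every attribute, the class-wise 5th-95th percentile interval ("stage"
#' range: stage I = normal, II = benign, III = malignant). Diagnostic / QC
#' output only; the classifier decision does not use it.
#'
#' @param fm Feature matrix ([extract_feature_matrix()]) containing all
#'   three classes.
#' @return Data frame with columns `attribute, class, lower, upper`.
#' @export
compute_stage_ranges <- function(fm) {
  if (!all(wd_classes %in% fm$label))
    stop("training data must contain all three classes", call. = FALSE)
  attrs <- feature_columns(fm)
  out <- do.call(rbind, lapply(wd_classes, function(cls) {
    sub <- fm[fm$label == cls, attrs, drop = FALSE]
    q <- t(vapply(sub, quantile, numeric(2), probs = c(0.05, 0.95),
                  names = FALSE))
    data.frame(attribute = attrs, class = cls, lower = q[, 1], upper = q[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Train the class reference for one modality
#'
#' Builds, per attribute: shared bin edges (optionally supplied, e.g. pooled
#' across modalities), a smoothed class distribution for each of normal /
#' benign / malignant, the pooled all-class distribution (used for the
#' entropy normalization of attribute weights), an exponential likelihood
#' rate per class on shifted values, and the stage ranges.
#'
#' @param fm Feature matrix restricted to one modality, all three classes
#'   labeled.
#' @param n_bins Bins per attribute (default 64).
#' @param bandwidth Histogram smoothing bandwidth in bins (default 1).
#' @param bin_edges Optional named list `attribute -> edges` to use instead
#'   of edges computed from `fm` (share edges across modalities by passing
#'   edges computed on the pooled feature matrix).
#' @return A `class_reference` object.
#' @export
train_reference <- function(fm, n_bins = 64, bandwidth = 1.0,
                            bin_edges = NULL) {
  modality <- unique(fm$modality)
  if (length(modality) != 1)
    stop("train_reference expects a single-modality feature matrix",
         call. = FALSE)
  if (!all(wd_classes %in% fm$label))
    stop("training data must contain all three classes", call. = FALSE)
  attrs <- feature_columns(fm)
  if (is.null(bin_edges))
    bin_edges <- lapply(setNames(attrs, attrs),
                        function(a) make_bin_edges(fm[[a]], n_bins))
  S <- smoothing_matrix(n_bins, bandwidth)
  dist_of <- function(rows) {
    vapply(attrs, function(a) {
      counts <- tabulate(bin_index(fm[rows, a], bin_edges[[a]]),
                         nbins = n_bins)
      smooth_counts(counts, S)
    }, numeric(n_bins))
  }
  dists <- lapply(setNames(wd_classes, wd_classes),
                  function(cls) dist_of(fm$label == cls))
  pooled <- dist_of(rep(TRUE, nrow(fm)))
  shift_min <- vapply(attrs, function(a) min(fm[[a]]), numeric(1))
  delta <- vapply(attrs, function(a) {
    r <- diff(range(fm[[a]]))
    1e-6 * if (r > 0) r else 1
  }, numeric(1))
  rates <- vapply(attrs, function(a) {
    vapply(wd_classes, function(cls)
      fit_exponential(shift_values(fm[fm$label == cls, a],
                                   shift_min[[a]], delta[[a]])),
      numeric(1))
  }, numeric(3))          # 3 classes x n_attr
  structure(list(
    modality = modality, attributes = attrs, n_bins = n_bins,
    bandwidth = bandwidth, bin_edges = bin_edges,
    dist = dists,                # class -> n_bins x n_attr matrix
    pooled = pooled,             # n_bins x n_attr
    rates = rates,               # 3 x n_attr, rows = classes
    shift_min = shift_min, shift_delta = delta,
    stages = compute_stage_ranges(fm),
    n_train = nrow(fm)),
    class = "class_reference")
}

#' Retrieve one trained class distribution
#'
#' @param reference A `class_reference`.
#' @param class,attribute Class label and attribute name.
#' @return A `feature_distribution`.
#' @export
get_distribution <- function(reference, class, attribute) {
  class <- match.arg(class, wd_classes)
  structure(list(bin_edges = reference$bin_edges[[attribute]],
                 probabilities = reference$dist[[class]][, attribute],
                 smoothing_bandwidth = reference$bandwidth),
            class = "feature_distribution")
}

#' Exponential log-likelihood of a feature vector under one class
#'
#' Sums `log(lambda) - lambda * x'` over attributes, with `x'` the test
#' value shifted by the training shift parameters (clamped to the positive
#' support).
#'
#' @param features Named numeric vector in the reference's attribute order.
#' @param reference A `class_reference`.
#' @param class Class label.
#' @return Scalar log-likelihood.
#' @export
class_likelihood <- function(features, reference, class) {
  class <- match.arg(class, wd_classes)
  attrs <- reference$attributes
  if (!all(attrs %in% names(features)))
    stop("feature vector does not match the reference's attributes",
         call. = FALSE)
  x <- shift_values(as.numeric(features[attrs]),
                    reference$shift_min[attrs],
                    reference$shift_delta[attrs])
  lam <- reference$rates[class, attrs]
  sum(log(lam) - lam * x)
}
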