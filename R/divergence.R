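# The three divergence measures and the entropy-normalized attribute
# weighting.
#
# All three measures are normalized to the shared range [0, 1] (JSD in base
# 2; squared Hellinger; triangular discrimination halved) so that a common
# set of decision bands applies whichever measure drives the classifier.

check_prob_pair <- function(p, q) {
  if (length(p) != length(q))
    stop("probability vectors must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0))
    stop("probability vectors must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("probability vectors must sum to 1", call. = FALSE)
}

#' Jensen-Shannon divergence
#'
#' The symmetrized, smoothed Kullback-Leibler divergence
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, logs in
#' base 2 so the value lies in `[0, 1]`; `0 * log(0/x)` is taken as 0.
#'
#' `variant = "binary"` instead evaluates a per-bin Bernoulli
#' Kullback-Leibler sum, `sum_i p_i log2(p_i/q_i) + (1-p_i)
#' log2((1-p_i)/(1-q_i))` — an alternative binary-coordinate reading kept
#' for comparison; it is not bounded by 1 and is not used by the default
#' pipeline.
#'
#' @param p,q Probability vectors of equal length summing to 1.
#' @param variant `"standard"` (default) or `"binary"`.
#' @return Scalar divergence; in `[0, 1]` for the standard variant.
#' @export
jsd <- function(p, q, variant = c("standard", "binary")) {
  variant <- match.arg(variant)
  check_prob_pair(p, q)
  if (variant == "binary") {
    term <- function(a, b) ifelse(a > 0, a * log2(a / pmax(b, 1e-300)), 0)
    return(sum(term(p, q) + term(1 - p, 1 - q)))
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' Squared Hellinger distance
#'
#' `H^2(p, q) = sum((sqrt(p) - sqrt(q))^2) / 2`, in `[0, 1]` with 1 at
#' disjoint support.
#'
#' @inheritParams jsd
#' @return Scalar in `[0, 1]`.
#' @export
hellinger <- function(p, q) {
  check_prob_pair(p, q)
  sum((sqrt(p) - sqrt(q))^2) / 2
}

#' Triangular discrimination
#'
#' `TD(p, q) = sum((p_i - q_i)^2 / (p_i + q_i)) / 2`; the raw triangular
#' discrimination has range `[0, 2]` and is halved here so all three
#' divergences share `[0, 1]`. Terms with `p_i + q_i = 0` contribute 0.
#'
#' @inheritParams jsd
#' @return Scalar in `[0, 1]`.
#' @export
triangle <- function(p, q) {
  check_prob_pair(p, q)
  s <- p + q
  i <- s > 0
  sum((p[i] - q[i])^2 / s[i]) / 2
}

# dispatch by kind ("JSD", "HD", "TD")
divergence_fun <- function(kind, jsd_variant = "standard") {
  switch(match.arg(kind, wd_divergences),
         JSD = function(p, q) jsd(p, q, variant = jsd_variant),
         HD = hellinger,
         TD = triangle)
}

# columnwise divergence between two n_bins x n_attr probability matrices;
# vectorized equivalents of the scalar functions above (validated there)
divergence_cols <- function(kind, P, Q, jsd_variant = "standard") {
  if (kind == "JSD" && jsd_variant == "standard") {
    M <- (P + Q) / 2
    tl <- function(A) colSums(ifelse(A > 0, A * log2(A / M), 0))
    (tl(P) + tl(Q)) / 2
  } else if (kind == "JSD") {
    t2 <- function(A, B) colSums(ifelse(A > 0,
                                        A * log2(A / pmax(B, 1e-300)), 0))
    t2(P, Q) + t2(1 - P, 1 - Q)
  } else if (kind == "HD") {
    colSums((sqrt(P) - sqrt(Q))^2) / 2
  } else {
    S <- P + Q
    colSums(ifelse(S > 0, (P - Q)^2 / pmax(S, 1e-300), 0)) / 2
  }
}

#' Entropy-normalized attribute weights
#'
#' For each attribute `i`: the average separability `W_av(i)` is the mean of
#' the chosen divergence over the three unordered class pairs of that
#' attribute's trained distributions. It is divided by the Shannon entropy
#' `H(i)` (bits, floored at `h_floor` so near-deterministic attributes do
#' not blow up) of the pooled all-class distribution, and the normalization
#' constant `z` is chosen so the weights sum to 1. If no attribute separates
#' the classes at all (`W_av` all ~0, e.g. on null data), weights fall back
#' to uniform.
#'
#' @param reference A trained `class_reference`.
#' @param divergence_kind `"JSD"`, `"HD"` or `"TD"`.
#' @param h_floor Entropy floor in bits (default 0.1).
#' @param jsd_variant Passed to [jsd()] when `divergence_kind = "JSD"`.
#' @return A `weight_vector`: list with `divergence_kind`, `weights` (named,
#'   summing to 1), `z`, `N`.
#' @export
compute_weights <- function(reference, divergence_kind = c("JSD", "HD", "TD"),
                            h_floor = 0.1, jsd_variant = "standard") {
  divergence_kind <- match.arg(divergence_kind)
  stopifnot(inherits(reference, "class_reference"))
  d <- reference$dist
  pairs <- list(c("normal", "benign"), c("normal", "malignant"),
                c("benign", "malignant"))
  w_av <- Reduce(`+`, lapply(pairs, function(pr)
    divergence_cols(divergence_kind, d[[pr[1]]], d[[pr[2]]],
                    jsd_variant))) / length(pairs)
  H <- -colSums(reference$pooled * log2(reference$pooled))
  raw <- w_av / pmax(H, h_floor)
  if (sum(raw) <= 1e-12) {
    w <- rep(1 / length(raw), length(raw))
    z <- NA_real_
  } else {
    z <- sum(raw)
    w <- raw / z
  }
  names(w) <- reference$attributes
  structure(list(divergence_kind = divergence_kind, weights = w, z = z,
                 N = reference$n_train),
            class = "weight_vector")
}
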