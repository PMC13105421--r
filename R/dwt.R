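# 2-D multilevel discrete wavelet transform, periodized boundary handling.
#
# Implemented directly (no DWT package is declared): analysis operators are
# built as decimated circulant matrices from the orthonormal scaling filter,
# so one level is three small matrix products. Periodization is used instead
# of the common symmetric extension because it is the boundary mode that
# gives exact dyadic subband sizes and makes the transform orthogonal
# (Parseval), which in turn makes normalized energy sum to 1 over subbands.

# Daubechies scaling filters h (orthonormal, sum = sqrt(2)), natural order.
wd_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(0.48296291314469025, 0.836516303737469,
           0.22414386804185735, -0.12940952255092145),
  db4  = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
           -0.027983769416859854, -0.18703481171909309,
           0.030841381835560764, 0.0328830116668852,
           -0.010597401785069032))

# cache of analysis operator pairs keyed by "<wavelet>:<n>"
.wd_op_cache <- new.env(parent = emptyenv())

# decimated circulant analysis operators: A (lowpass) and D (highpass),
# each n/2 x n; rows are even shifts of the filter, wrapped mod n.
dwt_operators <- function(wavelet, n) {
  key <- paste0(wavelet, ":", n)
  if (!is.null(.wd_op_cache[[key]])) return(.wd_op_cache[[key]])
  h <- wd_filters[[wavelet]]
  if (is.null(h))
    stop(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                 paste(names(wd_filters), collapse = ", ")), call. = FALSE)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)   # quadrature mirror filter
  A <- matrix(0, n %/% 2L, n)
  D <- matrix(0, n %/% 2L, n)
  for (k in seq_len(n %/% 2L)) {
    cols <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (j in seq_len(L)) {           # += handles wrap-around collisions
      A[k, cols[j]] <- A[k, cols[j]] + h[j]
      D[k, cols[j]] <- D[k, cols[j]] + g[j]
    }
  }
  ops <- list(A = A, D = D)
  .wd_op_cache[[key]] <- ops
  ops
}

#' Multilevel 2-D discrete wavelet decomposition
#'
#' Separable 2-D DWT with periodized boundary handling. At each level the
#' running approximation is split into approximation (CA), horizontal (CH),
#' vertical (CV) and diagonal (CD) detail subbands, each of half the side;
#' detail bands of every level are retained, the approximation only at the
#' deepest level. With `levels = 4` this yields 13 subbands
#' (`CA4, CH1..CH4, CV1..CV4, CD1..CD4`).
#'
#' The transform is orthogonal, so the sum of squared coefficients over all
#' retained subbands equals the sum of squared pixels.
#'
#' @param patch An [image_patch] or a square numeric matrix whose side is
#'   divisible by `2^levels`.
#' @param wavelet_name Wavelet filter: `"db4"` (default), `"db2"` or
#'   `"haar"`.
#' @param levels Number of decomposition levels (default 4).
#' @return A `subband_set`: list with `coefficients` (named list of
#'   matrices), `wavelet_name`, `boundary_mode`, `levels`.
#' @export
dwt_decompose <- function(patch, wavelet_name = "db4", levels = 4) {
  X <- if (inherits(patch, "image_patch")) patch$pixels else patch
  if (!is.matrix(X) || nrow(X) != ncol(X))
    stop("input must be a square matrix or image_patch", call. = FALSE)
  n <- nrow(X)
  if (n %% 2L^levels != 0L)
    stop(sprintf("side %d not divisible by 2^%d", n, levels), call. = FALSE)
  coefs <- list()
  for (l in seq_len(levels)) {
    ops <- dwt_operators(wavelet_name, nrow(X))
    A <- ops$A; D <- ops$D
    XA <- X %*% t(A); XD <- X %*% t(D)
    coefs[[paste0("CH", l)]] <- A %*% XD
    coefs[[paste0("CV", l)]] <- D %*% XA
    coefs[[paste0("CD", l)]] <- D %*% XD
    X <- A %*% XA
  }
  coefs[[paste0("CA", levels)]] <- X
  structure(list(coefficients = coefs, wavelet_name = wavelet_name,
                 boundary_mode = "periodization", levels = levels),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  sizes <- vapply(x$coefficients, nrow, integer(1))
  cat(sprintf("<subband_set %s, %d levels, periodization> bands: %s\n",
              x$wavelet_name, x$levels,
              paste(sprintf("%s[%d]", names(sizes), sizes), collapse = " ")))
  invisible(x)
}

# canonical subband order used everywhere (weights index into it)
subband_names <- function(levels = 4) {
  c(paste0("CA", levels),
    paste0("CH", seq_len(levels)),
    paste0("CV", seq_len(levels)),
    paste0("CD", seq_len(levels)))
}
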