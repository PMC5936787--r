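# Local cue extraction: the orientation vector (the raw bank responses),
# local luminance, and local luminance contrast, the latter two measured
# inside a raised-cosine weighted window.

#' Raised-cosine (radial Hann) window
#'
#' The 2-D weighting window used for local luminance and contrast:
#' `w(d) = 0.5 * (1 + cos(pi * d / R))` for radial distance `d <= R`
#' with `R = size / 2`, zero outside.
#'
#' @param size odd window side, >= 3.
#' @return list with `w` (size x size matrix, max 1 at the center) and
#'   `mu`, the sum of the weights.
#' @export
raised_cosine_window <- function(size) {
  if (length(size) != 1L || size %% 2L != 1L || size < 3L)
    stop("size must be an odd integer >= 3")
  r <- (size - 1L) %/% 2L
  R <- size / 2
  d <- sqrt(outer(seq.int(-r, r)^2, seq.int(-r, r)^2, "+"))
  w <- ifelse(d <= R, 0.5 * (1 + cos(pi * d / R)), 0)
  list(w = w, mu = sum(w))
}

#' Local luminance map
#'
#' Window-weighted mean of the image: `L(x, y) = (1/mu) * sum w_i I_i` over
#' the window centered at each pixel, reflected at borders.
#'
#' @param img grayscale image matrix.
#' @param window a window from [raised_cosine_window()].
#' @return matrix of local luminance, bounded by the image's range.
#' @export
luminance_map <- function(img, window) {
  check_gray(img)
  correlate2(img, window$w / window$mu)
}

#' Local luminance-contrast map
#'
#' Window-weighted variance of the image around the local luminance,
#' normalized by the squared luminance:
#' `C = (1/mu) * sum w_i (I_i - L)^2 / (L^2 + eps)`. The `eps` term guards
#' the division where L vanishes.
#'
#' @param img grayscale image matrix.
#' @param L luminance map computed with the same window.
#' @param window a window from [raised_cosine_window()].
#' @param eps denominator guard; default 1e-6.
#' @return nonnegative matrix.
#' @export
contrast_map <- function(img, L, window, eps = 1e-6) {
  check_gray(img)
  m2 <- correlate2(img^2, window$w / window$mu)
  v <- pmax(m2 - L^2, 0)   # weighted variance; clamp float negatives
  v / (L^2 + eps)
}

#' Center (CRF) orientation-vector average
#'
#' Smooths each component of the orientation vector field (the per-pixel
#' bank responses) with an isotropic Gaussian at the CRF scale, giving the
#' center orientation vector used by the orientation-dissimilarity weight.
#'
#' @param stack an `orientation_stack`.
#' @param sigma Gaussian scale of the averaging; defaults to the stack's.
#' @return h x w x n_theta array.
#' @export
crf_orientation_average <- function(stack, sigma = stack$sigma) {
  stopifnot(inherits(stack, "orientation_stack"))
  g <- gaussian_kernel(sigma)
  out <- stack$responses
  for (i in seq_len(dim(out)[3L])) out[, , i] <- correlate2(out[, , i], g)
  out
}

#' Surround (non-CRF) orientation-vector average
#'
#' Averages each component of the orientation vector field over the annular
#' surround, weighted by the distance kernel, giving the surround
#' orientation vector.
#'
#' @param stack an `orientation_stack`.
#' @param kernel a `distance_kernel`.
#' @return h x w x n_theta array.
#' @export
surround_orientation_average <- function(stack, kernel) {
  stopifnot(inherits(stack, "orientation_stack"),
            inherits(kernel, "distance_kernel"))
  out <- stack$responses
  for (i in seq_len(dim(out)[3L])) out[, , i] <- correlate2(out[, , i], kernel$w_d)
  out
}
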