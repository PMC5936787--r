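# Oriented Gaussian-derivative filter bank and winner-take-all CRF response.
#
# A V1 simple cell with preferred scale sigma is modeled as the first
# derivative of a 2-D Gaussian taken along an axis at angle theta from the
# column (x) axis; the cell's response is the absolute value of the image
# correlated with that kernel. The classical-receptive-field (CRF) response
# E is the per-pixel maximum over the bank.

#' Oriented first-derivative-of-Gaussian kernel
#'
#' Builds the kernel of one orientation-selective unit: the derivative of an
#' elongated 2-D Gaussian along the axis at angle `theta` (radians,
#' measured from the column axis; `theta = 0` differentiates across vertical
#' structure). The kernel support is the smallest odd square of side at
#' least `support_factor * sigma` and the entries sum to zero.
#'
#' @param theta orientation of the derivative axis, radians.
#' @param sigma Gaussian scale in pixels (> 0).
#' @param aspect ratio applied to the axis orthogonal to the derivative;
#'   1 (default) gives an isotropic Gaussian.
#' @param support_factor support side as a multiple of `sigma`; default 8.
#' @return numeric matrix with odd dimensions summing to ~0.
#' @export
gaussian_derivative_kernel <- function(theta, sigma, aspect = 1,
                                       support_factor = 8) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive number")
  side <- as.integer(ceiling(support_factor * sigma))
  if (side %% 2L == 0L) side <- side + 1L
  r <- (side - 1L) %/% 2L
  d <- seq.int(-r, r)
  # row index = y (down), col index = x (right)
  x <- matrix(d, side, side, byrow = TRUE)
  y <- matrix(d, side, side)
  xt <- x * cos(theta) + y * sin(theta)
  yt <- -x * sin(theta) + y * cos(theta)
  g <- exp(-(xt^2 + (aspect * yt)^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  -(xt / sigma^2) * g
}

#' Responses of the oriented filter bank
#'
#' Correlates the image with `n_theta` derivative kernels at orientations
#' `theta_i = (i - 1) * pi / n_theta` and takes absolute values, yielding
#' the rectified response of each orientation channel.
#'
#' @param img grayscale image matrix (values in \[0, 1\]).
#' @param sigma filter scale in pixels.
#' @param n_theta number of orientations (>= 2) spanning \[0, pi).
#' @param aspect,support_factor passed to [gaussian_derivative_kernel()].
#' @return an `orientation_stack`: list with `responses` (h x w x n_theta
#'   array, all >= 0), `thetas`, and `sigma`.
#' @export
orientation_responses <- function(img, sigma = 2, n_theta = 8, aspect = 1,
                                  support_factor = 8) {
  check_gray(img)
  if (n_theta < 2L) stop("n_theta must be at least 2")
  thetas <- (seq_len(n_theta) - 1) * pi / n_theta
  resp <- array(0, dim = c(nrow(img), ncol(img), n_theta))
  for (i in seq_len(n_theta)) {
    k <- gaussian_derivative_kernel(thetas[i], sigma, aspect, support_factor)
    resp[, , i] <- abs(correlate2(img, k))
  }
  structure(list(responses = resp, thetas = thetas, sigma = sigma),
            class = "orientation_stack")
}

#' Winner-take-all CRF response
#'
#' Per-pixel maximum over the orientation bank together with the index of
#' the winning orientation; ties are broken toward the lowest index.
#'
#' @param stack an `orientation_stack` from [orientation_responses()].
#' @return a `crf_response`: list with `E` (matrix >= 0), `argmax`
#'   (integer matrix of winning orientation indices), `thetas`, `sigma`.
#' @export
crf_response <- function(stack) {
  stopifnot(inherits(stack, "orientation_stack"))
  resp <- stack$responses
  n <- dim(resp)[3L]
  E <- resp[, , 1L]
  am <- matrix(1L, nrow(E), ncol(E))
  for (i in seq_len(n)[-1L]) {
    upd <- resp[, , i] > E       # strict: ties keep the lowest index
    E[upd] <- resp[, , i][upd]
    am[upd] <- i
  }
  structure(list(E = E, argmax = am, thetas = stack$thetas,
                 sigma = stack$sigma),
            class = "crf_response")
}
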