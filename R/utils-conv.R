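# Shared 2-D correlation machinery. Everything in the package that touches a
# neighborhood goes through these helpers so the border policy (symmetric
# mirror padding) is identical everywhere.

#' @keywords internal
#' @noRd
mirror_index <- function(i, n) {
  # symmetric (edge-repeating) reflection, valid for arbitrary overshoot
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

#' @keywords internal
#' @noRd
pad_reflect <- function(mat, pad_r, pad_c = pad_r) {
  h <- nrow(mat); w <- ncol(mat)
  ri <- mirror_index(seq.int(1L - pad_r, h + pad_r), h)
  ci <- mirror_index(seq.int(1L - pad_c, w + pad_c), w)
  mat[ri, ci, drop = FALSE]
}

#' Correlate an image with a kernel under reflected borders
#'
#' Direct (non-FFT) cross-correlation of a 2-D matrix with an odd-sided
#' kernel. Borders are handled by symmetric mirror padding, the single
#' border policy used throughout the package. The accumulation order is
#' fixed (kernel entries in column-major order), so repeated calls are
#' bitwise reproducible.
#'
#' @param img numeric matrix.
#' @param kern numeric matrix with odd dimensions.
#' @return matrix of the same dimensions as `img`.
#' @export
correlate2 <- function(img, kern) {
  stopifnot(is.matrix(img), is.matrix(kern))
  kh <- nrow(kern); kw <- ncol(kern)
  if (kh %% 2L == 0L || kw %% 2L == 0L)
    stop("kernel dimensions must be odd")
  h <- nrow(img); w <- ncol(img)
  rh <- (kh - 1L) %/% 2L; rw <- (kw - 1L) %/% 2L
  P <- pad_reflect(img, rh, rw)
  out <- matrix(0, h, w)
  nz <- which(kern != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(out)
  for (k in seq_len(nrow(nz))) {
    a <- nz[k, 1L]; b <- nz[k, 2L]
    out <- out + kern[a, b] * P[a:(a + h - 1L), b:(b + w - 1L)]
  }
  out
}

#' @keywords internal
#' @noRd
gaussian_kernel <- function(sigma, support_factor = 8) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  side <- as.integer(ceiling(support_factor * sigma))
  if (side %% 2L == 0L) side <- side + 1L
  r <- (side - 1L) %/% 2L
  d <- seq.int(-r, r)
  g1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

#' @keywords internal
#' @noRd
check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L) stop("image must be non-empty")
  if (!all(is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}
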