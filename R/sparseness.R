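# Sparseness-based texture suppression: windows of the gradient-magnitude
# histogram are scored with Hoyer's sparseness statistic (0 for a uniform
# histogram, 1 for a one-hot one); multiplying the contour response by the
# score attenuates dense texture, whose local gradient histograms are
# broad, while sparing clean contours, whose histograms are peaked.

#' Gradient magnitude by central differences
#'
#' @param img grayscale image matrix.
#' @return nonnegative matrix of Euclidean gradient magnitudes; border
#'   pixels use reflected neighbors (zero difference at the edge).
#' @export
gradient_magnitude <- function(img) {
  check_gray(img)
  kx <- matrix(c(-0.5, 0, 0.5), 1L, 3L)
  gx <- correlate2(img, kx)
  gy <- correlate2(img, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Hoyer sparseness of a nonnegative vector
#'
#' `(sqrt(n) - ||h||_1 / ||h||_2) / (sqrt(n) - 1)`: 0 for a uniform
#' vector, 1 for a one-hot vector, scale-invariant. An all-zero vector
#' returns 0 by convention (no structure). Setting `printed = TRUE` uses
#' `n` in place of `sqrt(n)`, an unbounded variant kept for auditability.
#'
#' @param h nonnegative numeric vector, length >= 2.
#' @param printed use the unbounded no-square-root variant; default FALSE.
#' @return sparseness value (in \[0, 1\] for the default variant).
#' @export
hoyer_sparseness <- function(h, printed = FALSE) {
  n <- length(h)
  if (n < 2L) stop("h must have length >= 2")
  if (any(h < 0)) stop("h must be nonnegative")
  l2 <- sqrt(sum(h^2))
  if (l2 == 0) return(0)
  l1 <- sum(h)
  if (printed) (n - l1 / l2) / (n - 1)
  else (sqrt(n) - l1 / l2) / (sqrt(n) - 1)
}

#' Windowed gradient-histogram sparseness map
#'
#' For each pixel, the gradient magnitudes in its `ws x ws` window
#' (reflected at borders) are histogrammed into `n_bins` equal-width bins
#' spanning \[0, global max magnitude\] and scored with
#' [hoyer_sparseness()]. A constant image (zero gradient everywhere)
#' yields the all-zero map.
#'
#' @param img grayscale image matrix.
#' @param ws odd window side; default 5.
#' @param n_bins histogram dimensionality; default 16.
#' @param printed use the unbounded sparseness variant; default FALSE.
#' @return a `sparseness_map`: list with `values` (matrix in \[0, 1\]),
#'   `ws`, `n_bins`.
#' @export
sparseness_map <- function(img, ws = 5, n_bins = 16, printed = FALSE) {
  check_gray(img)
  if (ws %% 2L != 1L || ws < 3L) stop("ws must be an odd integer >= 3")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  g <- gradient_magnitude(img)
  h <- nrow(g); w <- ncol(g)
  gmax <- max(g)
  if (gmax == 0) {
    vals <- matrix(0, h, w)
  } else {
    bin <- pmin(floor(g / gmax * n_bins), n_bins - 1) + 1  # 1..n_bins
    r <- (ws - 1L) %/% 2L
    Pb <- pad_reflect(bin, r)
    npix <- h * w
    counts <- matrix(0, npix, n_bins)
    for (a in seq_len(ws)) for (b in seq_len(ws)) {
      bk <- as.vector(Pb[a:(a + h - 1L), b:(b + w - 1L)])
      counts[cbind(seq_len(npix), bk)] <- counts[cbind(seq_len(npix), bk)] + 1
    }
    l1 <- rowSums(counts)
    l2 <- sqrt(rowSums(counts^2))
    sp <- if (printed) (n_bins - l1 / l2) / (n_bins - 1)
          else (sqrt(n_bins) - l1 / l2) / (sqrt(n_bins) - 1)
    vals <- matrix(sp, h, w)
  }
  structure(list(values = vals, ws = ws, n_bins = n_bins),
            class = "sparseness_map")
}

#' Modulate a contour response by its sparseness map
#'
#' Pointwise product of the inhibited response and the sparseness score;
#' the result never exceeds the input response.
#'
#' @param res contour response matrix.
#' @param s a `sparseness_map` or plain matrix of the same shape.
#' @return matrix, `res * s` pointwise.
#' @export
apply_sparseness <- function(res, s) {
  if (inherits(s, "sparseness_map")) s <- s$values
  if (!identical(dim(res), dim(s)))
    stop("response and sparseness map must have identical dimensions")
  res * s
}
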