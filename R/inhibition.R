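# Surround inhibition: the annular distance kernel, per-cue inhibitory
# weights from center-surround dissimilarity, scale-guided fusion, and
# half-wave-rectified suppression of the CRF response.

#' Annular surround distance kernel
#'
#' Distance weighting of the non-classical receptive field: a
#' difference-of-Gaussians `G_{outer*sigma} - G_{sigma}` with negative
#' values clipped to zero (so the center carries no weight) and the result
#' L1-normalized. Normalization to 1 bounds the cue weights by 1.
#'
#' @param sigma CRF scale in pixels (> 0).
#' @param outer_factor scale ratio of the outer Gaussian; default 4.
#' @return a `distance_kernel`: list with `w_d` (nonnegative matrix summing
#'   to 1, zero at the center) and `sigma`.
#' @export
distance_kernel <- function(sigma, outer_factor = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive number")
  s_out <- outer_factor * sigma
  r <- as.integer(ceiling(4 * s_out))
  side <- 2L * r + 1L
  d2 <- outer(seq.int(-r, r)^2, seq.int(-r, r)^2, "+")
  g_out <- exp(-d2 / (2 * s_out^2)) / (2 * pi * s_out^2)
  g_in <- exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  w <- pmax(g_out - g_in, 0)
  w <- w / sum(w)
  structure(list(w_d = w, sigma = sigma), class = "distance_kernel")
}

# Joint position-aware computation of the three cue weights. `positions`
# is a vector of linear (column-major) pixel indices, or NULL for every
# pixel. The loop runs offset-major over the nonzero entries of w_d, so
# results at a given pixel do not depend on which other pixels are in
# `positions` -- the accelerated paths are bitwise identical to the full
# field at the pixels they actually compute.
#' @keywords internal
#' @noRd
cue_weights_at <- function(theta_crf, stack, L, C, kernel,
                           sigma_dtheta, sigma_dl, sigma_dc,
                           positions = NULL) {
  h <- nrow(L); w <- ncol(L)
  if (is.null(positions)) positions <- seq_len(h * w)
  m <- length(positions)
  wd <- kernel$w_d
  r <- (nrow(wd) - 1L) %/% 2L
  Hp <- h + 2L * r
  i0 <- (positions - 1L) %% h + 1L
  j0 <- (positions - 1L) %/% h + 1L
  base <- (j0 + r - 1L) * Hp + (i0 + r)          # padded linear index of center
  nz <- which(wd != 0)
  a <- (nz - 1L) %% nrow(wd) + 1L
  b <- (nz - 1L) %/% nrow(wd) + 1L
  off <- (b - r - 1L) * Hp + (a - r - 1L)        # padded index offset
  wv <- wd[nz]

  Pl <- pad_reflect(L, r)
  Pc <- pad_reflect(C, r)
  nth <- dim(stack$responses)[3L]
  Pt <- vector("list", nth)
  for (q in seq_len(nth)) Pt[[q]] <- pad_reflect(stack$responses[, , q], r)

  cl <- L[positions]; cc <- C[positions]
  tl2 <- 2 * sigma_dl^2; tc2 <- 2 * sigma_dc^2
  accL <- numeric(m); accC <- numeric(m)
  accT <- matrix(0, m, nth)
  for (k in seq_along(nz)) {
    idx <- base + off[k]
    accL <- accL + wv[k] * exp(-(cl - Pl[idx])^2 / tl2)
    accC <- accC + wv[k] * exp(-(cc - Pc[idx])^2 / tc2)
    for (q in seq_len(nth)) accT[, q] <- accT[, q] + wv[k] * Pt[[q]][idx]
  }
  tc_mat <- matrix(0, m, nth)
  for (q in seq_len(nth)) tc_mat[, q] <- theta_crf[, , q][positions]
  d2 <- rowSums((tc_mat - accT)^2)
  list(w_theta = exp(-d2 / (2 * sigma_dtheta^2)), w_l = accL, w_c = accC,
       positions = positions)
}

#' Orientation-dissimilarity inhibitory weight
#'
#' Gaussian similarity between the center and surround orientation vectors:
#' `W_theta = exp(-||theta_crf - theta_ncrf||^2 / (2 * sigma_dtheta^2))`;
#' 1 where the vectors agree, toward 0 as they diverge (weak inhibition at
#' orientation-discontinuous contours).
#'
#' @param theta_crf,theta_ncrf h x w x n_theta arrays (center and surround
#'   orientation-vector fields).
#' @param sigma_dtheta orientation sensitivity; default 0.2.
#' @return matrix in \[0, 1\].
#' @export
orientation_weight <- function(theta_crf, theta_ncrf, sigma_dtheta = 0.2) {
  if (!identical(dim(theta_crf), dim(theta_ncrf)))
    stop("orientation fields must have identical dimensions")
  if (sigma_dtheta <= 0) stop("sigma_dtheta must be positive")
  d2 <- apply((theta_crf - theta_ncrf)^2, c(1L, 2L), sum)
  exp(-d2 / (2 * sigma_dtheta^2))
}

#' Scalar-cue inhibitory weight
#'
#' For a scalar cue map (luminance or contrast), the distance-kernel
#' weighted sum over the surround of the Gaussian similarity between the
#' center value and each surround value. Because the kernel sums to 1 the
#' result lies in \[0, 1\]: near 1 in homogeneous texture (strong
#' inhibition), near 0 where the center differs from its whole surround.
#'
#' @param cue_map scalar cue matrix.
#' @param sigma_cue similarity sensitivity (> 0); 0.05 for both luminance
#'   and contrast by default in [smci_config()].
#' @param kernel a `distance_kernel`.
#' @return matrix in \[0, 1\].
#' @export
scalar_cue_weight <- function(cue_map, sigma_cue, kernel) {
  check_gray(cue_map)
  if (sigma_cue <= 0) stop("sigma_cue must be positive")
  stopifnot(inherits(kernel, "distance_kernel"))
  h <- nrow(cue_map); w <- ncol(cue_map)
  wd <- kernel$w_d
  r <- (nrow(wd) - 1L) %/% 2L
  P <- pad_reflect(cue_map, r)
  out <- matrix(0, h, w)
  nz <- which(wd != 0, arr.ind = TRUE)
  t2 <- 2 * sigma_cue^2
  for (k in seq_len(nrow(nz))) {
    a <- nz[k, 1L]; b <- nz[k, 2L]
    out <- out + wd[a, b] *
      exp(-(cue_map - P[a:(a + h - 1L), b:(b + w - 1L)])^2 / t2)
  }
  out
}

#' Scale-guided combination of the cue weights
#'
#' Fuses the three cue weights per pixel: where the min-max normalized
#' fine-scale CRF response exceeds the normalized coarse-scale (2 sigma)
#' response, the maximum of the three weights is taken (the pixel behaves
#' like texture, inhibit hard); otherwise the minimum (likely contour,
#' inhibit gently). A constant response map normalizes to all zeros.
#'
#' @param w_theta,w_l,w_c weight matrices in \[0, 1\].
#' @param E_s,E_2s CRF response matrices at scales sigma and 2 * sigma
#'   (either `crf_response` objects or plain matrices).
#' @return matrix in \[0, 1\].
#' @export
combine_weights <- function(w_theta, w_l, w_c, E_s, E_2s) {
  if (inherits(E_s, "crf_response")) E_s <- E_s$E
  if (inherits(E_2s, "crf_response")) E_2s <- E_2s$E
  stopifnot(identical(dim(w_theta), dim(w_l)),
            identical(dim(w_theta), dim(w_c)),
            identical(dim(w_theta), dim(E_s)),
            identical(dim(w_theta), dim(E_2s)))
  norm01 <- function(E) {
    rg <- range(E)
    if (rg[2L] == rg[1L]) return(array(0, dim = dim(E)))
    (E - rg[1L]) / (rg[2L] - rg[1L])
  }
  fine <- norm01(E_s) - norm01(E_2s) > 0
  out <- pmin(w_theta, w_l, w_c)
  mx <- pmax(w_theta, w_l, w_c)
  out[fine] <- mx[fine]
  out
}

#' Half-wave-rectified surround suppression
#'
#' The inhibited contour response:
#' `res = max(0, E - alpha * w_com * (E correlated with w_d))`. The
#' correlation spreads the CRF response over the surround; the combined
#' weight gates how much of that surround activity inhibits each pixel.
#'
#' @param E CRF response (`crf_response` or matrix).
#' @param w_com combined weight matrix in \[0, 1\].
#' @param kernel a `distance_kernel`.
#' @param alpha inhibition strength (>= 0); default 5.
#' @return nonnegative matrix, pointwise <= E.
#' @export
suppress <- function(E, w_com, kernel, alpha = 5) {
  if (inherits(E, "crf_response")) E <- E$E
  if (alpha < 0) stop("alpha must be nonnegative")
  stopifnot(identical(dim(E), dim(w_com)), inherits(kernel, "distance_kernel"))
  inhib <- correlate2(E, kernel$w_d)
  pmax(E - alpha * w_com * inhib, 0)
}
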