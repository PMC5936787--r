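# Acceleration of the inhibitory-weight computation: prior filtering of
# low-response pixels, uniform-sampling reconstruction of the weight
# fields, and their combination. An instrumented counter records how many
# pixel locations had their weights explicitly computed.

#' Prior-filtering mask
#'
#' Marks the pixels whose CRF response reaches a fraction of the global
#' maximum response; only those pixels get a full weight computation, the
#' rest are assigned maximal inhibition.
#'
#' @param E CRF response (`crf_response` or matrix).
#' @param fraction threshold as a fraction of `max(E)`, in \[0, 1\].
#' @return integer 0/1 matrix; 1 where `E >= fraction * max(E)`.
#' @export
prior_mask <- function(E, fraction) {
  if (inherits(E, "crf_response")) E <- E$E
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  loc <- matrix(0L, nrow(E), ncol(E))
  loc[E - fraction * max(E) >= 0] <- 1L
  loc
}

#' Uniformly sampled grid positions
#'
#' The pixel locations at which weights are explicitly computed under a
#' sampling mode. With stride 2, mode `"x"` keeps the odd columns (all
#' rows), `"y"` the odd rows, `"xy"` their intersection grid, `"none"`
#' every pixel. The last row and column are always included so
#' reconstruction never extrapolates.
#'
#' @param dims integer vector `c(h, w)`.
#' @param mode one of `"none"`, `"x"`, `"y"`, `"xy"`.
#' @param stride sampling period; only 2 is supported (the reconstruction
#'   stencils are specific to it).
#' @return logical h x w matrix, TRUE at sampled positions.
#' @export
sampled_positions <- function(dims, mode = c("none", "x", "y", "xy"),
                              stride = 2L) {
  mode <- match.arg(mode)
  if (stride != 2L) stop("only stride 2 is supported")
  h <- dims[1L]; w <- dims[2L]
  if (h < stride || w < stride) mode <- "none"  # degenerate: sample all
  rows <- rep(TRUE, h); cols <- rep(TRUE, w)
  if (mode %in% c("y", "xy")) {
    rows <- rep(FALSE, h); rows[seq.int(1L, h, 2L)] <- TRUE; rows[h] <- TRUE
  }
  if (mode %in% c("x", "xy")) {
    cols <- rep(FALSE, w); cols[seq.int(1L, w, 2L)] <- TRUE; cols[w] <- TRUE
  }
  outer(rows, cols, "&")
}

#' Reconstruct a weight field from its sampled lines
#'
#' Fills the unsampled positions of a field known on the sampled grid of
#' [sampled_positions()] using the fixed-coefficient stencils: a missing
#' point between two sampled neighbors takes 2/3 of the lower-index
#' neighbor and 1/3 of the higher-index one (nearby units dominate); under
#' two-direction sampling the remaining center points take 1/3 of the
#' reconstructed point above and to the left and 1/6 of the ones below and
#' to the right, so an indicator at a sampled corner expands to 4/9, 2/9,
#' 2/9, 1/9 at the center.
#'
#' @param field matrix with valid values at every sampled position
#'   (unsampled entries are ignored and may be NA).
#' @param mode sampling mode the field was sampled under.
#' @param stride sampling period (2).
#' @return fully populated matrix.
#' @export
reconstruct_field <- function(field, mode = c("none", "x", "y", "xy"),
                              stride = 2L) {
  mode <- match.arg(mode)
  samp <- sampled_positions(dim(field), mode, stride)
  if (anyNA(field[samp]))
    stop("missing value at a sampled stencil position")
  if (mode == "none") return(field)
  h <- nrow(field); w <- ncol(field)
  out <- field
  srow <- samp[, 1L]; scol <- samp[1L, ]  # sampled row/col indicator
  if (mode == "x") {
    for (j in which(!scol)) out[, j] <- 2 / 3 * out[, j - 1L] + 1 / 3 * out[, j + 1L]
  } else if (mode == "y") {
    for (i in which(!srow)) out[i, ] <- 2 / 3 * out[i - 1L, ] + 1 / 3 * out[i + 1L, ]
  } else {
    rows_s <- which(apply(samp, 1L, any))   # fully/partially sampled rows
    cols_s <- which(apply(samp, 2L, any))
    rs <- logical(h); rs[rows_s] <- TRUE
    cs <- logical(w); cs[cols_s] <- TRUE
    # stage 1: points on sampled rows between sampled columns, and vice versa
    for (j in which(!cs))
      out[rs, j] <- 2 / 3 * out[rs, j - 1L] + 1 / 3 * out[rs, j + 1L]
    for (i in which(!rs))
      out[i, cs] <- 2 / 3 * out[i - 1L, cs] + 1 / 3 * out[i + 1L, cs]
    # stage 2: centers from the four stage-1 neighbors
    for (i in which(!rs)) {
      jj <- which(!cs)
      out[i, jj] <- 1 / 3 * out[i - 1L, jj] + 1 / 3 * out[i, jj - 1L] +
        1 / 6 * out[i + 1L, jj] + 1 / 6 * out[i, jj + 1L]
    }
  }
  out
}

#' Inhibitory weight fields under full or accelerated computation
#'
#' Computes the three cue weight fields (orientation, luminance, contrast)
#' with optional prior filtering and uniform sampling. Weights are
#' explicitly evaluated only at sampled positions that pass the prior mask;
#' masked-out pixels receive weight 1 (maximal inhibition, so sub-threshold
#' background is suppressed); remaining unsampled pixels are reconstructed
#' with the sampling stencils. The number of explicitly evaluated pixel
#' locations is returned so work reduction can be measured.
#'
#' Results at explicitly computed pixels are bitwise identical to the full
#' computation, so `prior_fraction = 0` with `sampling = "none"`
#' reproduces the exact MCI weight fields.
#'
#' @param stack `orientation_stack` at the CRF scale.
#' @param L,C luminance and contrast maps.
#' @param E CRF response at the same scale (`crf_response` or matrix).
#' @param kernel a `distance_kernel`.
#' @param config a [smci_config()] list.
#' @param prior_fraction prior-filtering fraction, or NULL for no mask.
#' @param sampling sampling mode, one of `"none"`, `"x"`, `"y"`, `"xy"`.
#' @return list with `w_theta`, `w_l`, `w_c` (full matrices),
#'   `n_evaluated` (explicit weight evaluations, pixel locations) and
#'   `n_pixels`.
#' @export
inhibition_weights <- function(stack, L, C, E, kernel, config = smci_config(),
                               prior_fraction = NULL, sampling = "none") {
  if (inherits(E, "crf_response")) E <- E$E
  h <- nrow(L); w <- ncol(L)
  theta_crf <- crf_orientation_average(stack, config$sigma)
  if (config$ncrf_weighting == "gaussian") {
    # alternative surround average: wide Gaussian instead of the annulus
    gk <- gaussian_kernel(config$surround_outer_factor * config$sigma,
                          support_factor = 4)
    surr <- structure(list(w_d = gk, sigma = kernel$sigma),
                      class = "distance_kernel")
  } else surr <- kernel

  samp <- sampled_positions(c(h, w), sampling, config$stride)
  pass <- if (is.null(prior_fraction)) matrix(TRUE, h, w) else
    prior_mask(E, prior_fraction) == 1L
  positions <- which(samp & pass)

  cw <- cue_weights_at(theta_crf, stack, L, C, surr,
                       config$sigma_dtheta, config$sigma_dl, config$sigma_dc,
                       positions)
  fill <- function(values) {
    f <- matrix(NA_real_, h, w)
    f[positions] <- values
    f[!pass] <- 1                        # masked out: maximal inhibition
    if (sampling != "none") {
      need <- is.na(f)
      if (any(need)) {
        rec <- reconstruct_field(f, sampling, config$stride)
        f[need] <- rec[need]
      }
    }
    f
  }
  list(w_theta = fill(cw$w_theta), w_l = fill(cw$w_l), w_c = fill(cw$w_c),
       n_evaluated = length(positions), n_pixels = h * w)
}
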