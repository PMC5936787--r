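# End-to-end detection pipeline: filter bank -> local cues -> inhibitory
# weights (full or accelerated) -> suppression -> optional sparseness
# modulation -> thinning and binarization.

#' Detect contours in a grayscale image
#'
#' Runs the full surround-inhibition detector. `mode` selects how the
#' per-pixel inhibitory weights are obtained:
#' \describe{
#'   \item{`mci`}{full computation at every pixel.}
#'   \item{`prior`}{weights computed only where the CRF response reaches
#'     `prior_fraction` (default 0.30) of the image maximum; elsewhere
#'     weight 1.}
#'   \item{`sample-x`, `sample-y`, `sample-xy`}{weights computed on
#'     uniformly sampled lines (stride 2) and reconstructed elsewhere with
#'     fixed stencils.}
#'   \item{`combined`}{prior filtering at `combined_fraction` (default
#'     0.10) plus one-direction sampling.}
#' }
#'
#' @param img grayscale matrix in \[0, 1\] (or an `smci_scene`).
#' @param config an [smci_config()] list.
#' @param mode weight-computation mode; see Details.
#' @param sparse apply sparseness modulation; default TRUE.
#' @param prior_fraction overrides the mode's prior fraction (NULL keeps
#'   the config default for the mode).
#' @return an `smci_detection` list: `E` (CRF response), `w_com`
#'   (combined weight field), `res` (inhibited response), `sparseness`
#'   (map or NULL), `final`, `thinned`, `binary`, plus `mode`,
#'   `weight_evals` (explicitly evaluated pixel locations), `n_pixels`,
#'   and the `config`.
#' @export
smci_detect <- function(img, config = smci_config(),
                        mode = c("mci", "prior", "sample-x", "sample-y",
                                 "sample-xy", "combined"),
                        sparse = TRUE, prior_fraction = NULL) {
  mode <- match.arg(mode)
  if (inherits(img, "smci_scene")) img <- img$image
  check_gray(img)
  if (min(img) < 0 || max(img) > 1) stop("image values must lie in [0, 1]")

  stack <- orientation_responses(img, config$sigma, config$n_theta,
                                 config$aspect, config$support_factor)
  crf <- crf_response(stack)
  stack2 <- orientation_responses(img, 2 * config$sigma, config$n_theta,
                                  config$aspect, config$support_factor)
  crf2 <- crf_response(stack2)

  win <- raised_cosine_window(config$window_size)
  L <- luminance_map(img, win)
  C <- contrast_map(img, L, win, config$eps)
  kern <- distance_kernel(config$sigma, config$surround_outer_factor)

  frac <- switch(mode,
                 mci = NULL,
                 prior = if (is.null(prior_fraction)) config$prior_fraction
                         else prior_fraction,
                 combined = if (is.null(prior_fraction))
                   config$combined_fraction else prior_fraction,
                 `sample-x` = , `sample-y` = , `sample-xy` = prior_fraction)
  sampling <- switch(mode, mci = , prior = "none", `sample-x` = "x",
                     `sample-y` = "y", `sample-xy` = "xy", combined = "x")

  wts <- inhibition_weights(stack, L, C, crf$E, kern, config,
                            prior_fraction = frac, sampling = sampling)
  w_com <- combine_weights(wts$w_theta, wts$w_l, wts$w_c, crf$E, crf2$E)
  res <- suppress(crf$E, w_com, kern, config$alpha)

  sp <- NULL
  final <- res
  if (isTRUE(sparse)) {
    sp <- sparseness_map(img, config$ws, config$n_bins,
                         config$printed_sparseness)
    final <- apply_sparseness(res, sp)
  }
  thinned <- nonmax_suppress(final, crf)
  binary <- hysteresis(thinned, config$p, config$low_ratio)

  structure(list(E = crf$E, argmax = crf$argmax, w_com = w_com, res = res,
                 sparseness = sp, final = final, thinned = thinned,
                 binary = binary, mode = mode, sparse = isTRUE(sparse),
                 weight_evals = wts$n_evaluated, n_pixels = wts$n_pixels,
                 config = config),
            class = "smci_detection")
}

#' @export
print.smci_detection <- function(x, ...) {
  cat(sprintf("smci detection (%s%s): %d x %d image\n", x$mode,
              if (x$sparse) " + sparseness" else "", nrow(x$E), ncol(x$E)))
  cat(sprintf("  weight evaluations: %d / %d pixels (%.1f%%)\n",
              x$weight_evals, x$n_pixels,
              100 * x$weight_evals / x$n_pixels))
  cat(sprintf("  edge pixels after hysteresis: %d\n", sum(x$binary)))
  invisible(x)
}

#' @export
print.edge_eval <- function(x, ...) {
  cat(sprintf("P = %.3f, R = %.3f, F = %.3f (%d/%d pred, %d/%d gt matched, tol %g px)\n",
              x$precision, x$recall, x$f_score, x$matched, x$n_pred,
              x$matched, x$n_gt, x$tolerance))
  invisible(x)
}
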