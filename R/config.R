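# Model configuration. Defaults follow the published parameter table of
# the detector (alpha = 5, sigma_dtheta = 0.2, sigma_dl = sigma_dc = 0.05,
# hysteresis p = 1, sparseness window ws = 5); the remaining knobs are
# package defaults documented in the methods vignette.

#' Detector configuration
#'
#' Builds the full parameter list consumed by [smci_detect()] and the
#' lower-level operations. Any subset of parameters may be overridden.
#'
#' @param n_theta number of filter orientations; default 8.
#' @param sigma CRF filter scale in pixels; default 2 (the coarse scale of
#'   the scale-guided combination is fixed at `2 * sigma`).
#' @param aspect Gaussian aspect ratio of the derivative filter; default 1.
#' @param support_factor filter support as a multiple of sigma; default 8.
#' @param window_size odd side of the raised-cosine cue window; default 11.
#' @param eps contrast denominator guard; default 1e-6.
#' @param alpha surround-inhibition strength; default 5.
#' @param sigma_dtheta,sigma_dl,sigma_dc inhibition sensitivities of the
#'   orientation, luminance and contrast cues; defaults 0.2, 0.05, 0.05.
#' @param surround_outer_factor outer/inner scale ratio of the surround
#'   annulus; default 4.
#' @param ncrf_weighting surround orientation averaging, `"wd"` (annulus,
#'   default) or `"gaussian"`.
#' @param prior_fraction prior-filtering threshold fraction; default 0.30.
#' @param combined_fraction prior fraction of the combined mode; default
#'   0.10.
#' @param stride uniform-sampling period; fixed at 2.
#' @param ws sparseness window side; default 5.
#' @param n_bins sparseness histogram bins; default 16.
#' @param printed_sparseness use the unbounded no-square-root sparseness
#'   variant; default FALSE.
#' @param p fraction of candidate edge pixels retained by hysteresis;
#'   default 1.
#' @param low_ratio hysteresis low/high threshold ratio; default 0.4.
#' @param tolerance evaluation match distance in pixels; default 2.
#' @return a named list of class `smci_config`.
#' @export
smci_config <- function(n_theta = 8L, sigma = 2, aspect = 1,
                        support_factor = 8, window_size = 11L, eps = 1e-6,
                        alpha = 5, sigma_dtheta = 0.2, sigma_dl = 0.05,
                        sigma_dc = 0.05, surround_outer_factor = 4,
                        ncrf_weighting = c("wd", "gaussian"),
                        prior_fraction = 0.30, combined_fraction = 0.10,
                        stride = 2L, ws = 5L, n_bins = 16L,
                        printed_sparseness = FALSE, p = 1, low_ratio = 0.4,
                        tolerance = 2) {
  ncrf_weighting <- match.arg(ncrf_weighting)
  cfg <- list(n_theta = as.integer(n_theta), sigma = sigma, aspect = aspect,
              support_factor = support_factor,
              window_size = as.integer(window_size), eps = eps, alpha = alpha,
              sigma_dtheta = sigma_dtheta, sigma_dl = sigma_dl,
              sigma_dc = sigma_dc,
              surround_outer_factor = surround_outer_factor,
              ncrf_weighting = ncrf_weighting,
              prior_fraction = prior_fraction,
              combined_fraction = combined_fraction,
              stride = as.integer(stride), ws = as.integer(ws),
              n_bins = as.integer(n_bins),
              printed_sparseness = isTRUE(printed_sparseness), p = p,
              low_ratio = low_ratio, tolerance = tolerance)
  validate_config(cfg)
  structure(cfg, class = "smci_config")
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  with(cfg, {
    if (n_theta < 2L) stop("n_theta must be >= 2")
    if (sigma <= 0) stop("sigma must be positive")
    if (sigma_dtheta <= 0 || sigma_dl <= 0 || sigma_dc <= 0)
      stop("inhibition sensitivities must be positive")
    if (alpha < 0) stop("alpha must be nonnegative")
    if (window_size %% 2L != 1L || window_size < 3L)
      stop("window_size must be an odd integer >= 3")
    if (prior_fraction < 0 || prior_fraction > 1 ||
        combined_fraction < 0 || combined_fraction > 1)
      stop("prior fractions must be in [0, 1]")
    if (stride != 2L) stop("stride must be 2")
    if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  })
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Reads a YAML file whose keys are [smci_config()] argument names and
#' merges them over the defaults; `overrides` (e.g. parsed CLI flags) win
#' over the file.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list applied last.
#' @return an `smci_config` list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(smci_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(smci_config, vals)
}
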