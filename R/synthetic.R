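# Seeded synthetic scenes: a salient contour over a background of random
# oriented line-segment texture, with ground-truth masks, so every stage
# of the detector is testable without external data. The scenes emulate
# the structure the surround-inhibition mechanism targets: a contour
# occupying a small fraction of the image, embedded in dense clutter.

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @keywords internal
#' @noRd
draw_segment <- function(canvas, mask, r0, c0, angle, len, value, forbid) {
  h <- nrow(canvas); w <- ncol(canvas)
  t <- seq(-len / 2, len / 2, by = 0.5)
  rr <- round(r0 + t * sin(angle)); cc <- round(c0 + t * cos(angle))
  ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
  idx <- unique(cbind(rr[ok], cc[ok]))
  if (nrow(idx) > 0) {
    lin <- (idx[, 2L] - 1L) * h + idx[, 1L]
    lin <- lin[!forbid[lin]]
    canvas[lin] <- value
    mask[lin] <- 1L
  }
  list(canvas = canvas, mask = mask)
}

#' Generate a synthetic contour-in-texture scene
#'
#' Builds a grayscale image containing one salient structure (a luminance
#' step edge, a disc, or a bright bar) over a background cluttered with
#' short randomly oriented line segments, together with a one-pixel-wide
#' ground-truth contour mask and a texture mask (disjoint from the contour
#' and a 2-pixel guard band around it). The same seed always yields the
#' identical scene.
#'
#' @param kind `"step-edge"`, `"disc-on-texture"` or `"bar-in-clutter"`.
#' @param size image side in pixels, >= 32; default 64.
#' @param texture_density fraction controlling how many texture segments
#'   are drawn, in \[0, 1\]; default 0.15.
#' @param contrast luminance contrast of the salient structure, in
#'   \[0, 1\]; default 0.5.
#' @param seed RNG seed; the global RNG state is left untouched.
#' @return an `smci_scene`: list with `image` (matrix in \[0, 1\]),
#'   `contour_mask`, `texture_mask` (0/1 matrices), `kind`, `seed`.
#' @export
generate_scene <- function(kind = c("disc-on-texture", "step-edge",
                                    "bar-in-clutter"),
                           size = 64L, texture_density = 0.15,
                           contrast = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 32L) stop("size must be >= 32")
  if (texture_density < 0 || texture_density > 1)
    stop("texture_density must be in [0, 1]")
  with_local_seed(seed, {
    h <- w <- as.integer(size)
    lo <- 0.5 - contrast / 2
    hi <- 0.5 + contrast / 2
    img <- matrix(lo, h, w)
    contour <- matrix(0L, h, w)
    if (kind == "step-edge") {
      m <- w %/% 2L
      img[, (m + 1L):w] <- hi
      contour[, m] <- 1L
    } else if (kind == "disc-on-texture") {
      ctr <- (size + 1) / 2
      rad <- size / 4
      d <- sqrt(outer((seq_len(h) - ctr)^2, (seq_len(w) - ctr)^2, "+"))
      img[d <= rad] <- hi
      phi <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rad * 4))
      rr <- pmin(h, pmax(1, round(ctr + rad * sin(phi))))
      cc <- pmin(w, pmax(1, round(ctr + rad * cos(phi))))
      contour[cbind(rr, cc)] <- 1L
    } else {  # bar-in-clutter
      ang <- stats::runif(1, 0, pi)
      ctr <- (size + 1) / 2
      len <- size / 2
      t <- seq(-len / 2, len / 2, by = 0.5)
      rr <- round(ctr + t * sin(ang)); cc <- round(ctr + t * cos(ang))
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      idx <- unique(cbind(rr[ok], cc[ok]))
      img[idx] <- hi
      contour[idx] <- 1L
    }
    # guard band: no texture within 2 px of the contour
    guard <- contour
    for (dr in -2:2) for (dc in -2:2) {
      rs <- seq_len(h); cs <- seq_len(w)
      rv <- rs[rs + dr >= 1L & rs + dr <= h]
      cv <- cs[cs + dc >= 1L & cs + dc <= w]
      guard[rv, cv] <- pmax(guard[rv, cv], contour[rv + dr, cv + dc])
    }
    forbid <- guard == 1L
    if (kind == "disc-on-texture") {
      ctr <- (size + 1) / 2
      d <- sqrt(outer((seq_len(h) - ctr)^2, (seq_len(w) - ctr)^2, "+"))
      forbid <- forbid | d <= size / 4   # keep the disc interior clean
    }
    texture <- matrix(0L, h, w)
    n_seg <- round(texture_density * h * w / 12)
    for (s in seq_len(n_seg)) {
      val <- 0.5 + stats::runif(1, -0.5, 0.5) * contrast
      res <- draw_segment(img, texture,
                          r0 = stats::runif(1, 1, h),
                          c0 = stats::runif(1, 1, w),
                          angle = stats::runif(1, 0, pi),
                          len = stats::runif(1, 4, 8),
                          value = min(1, max(0, val)), forbid = forbid)
      img <- res$canvas; texture <- res$mask
    }
    structure(list(image = img, contour_mask = contour,
                   texture_mask = texture, kind = kind,
                   seed = as.integer(seed)),
              class = "smci_scene")
  })
}
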