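# Post-processing of the real-valued contour response (non-maximum
# suppression, hysteresis thresholding) and boundary evaluation with
# precision / recall / F.

#' Non-maximum suppression along the winning orientation
#'
#' Thins the response by keeping a pixel only if it is a local maximum
#' along the derivative axis of its winning orientation (the axis crossing
#' the contour). Each orientation is quantized to one of the four
#' 8-neighbor axes; a pixel survives iff its value is strictly greater than
#' the preceding neighbor and at least the following neighbor along that
#' axis (keep-first tie rule, so an equal plateau keeps its first pixel).
#' Neighbors beyond the border count as zero.
#'
#' @param res nonnegative response matrix.
#' @param orientation `crf_response` or integer matrix of winning
#'   orientation indices (into `thetas`).
#' @param thetas orientations corresponding to the indices; required when
#'   `orientation` is a plain matrix.
#' @return thinned response matrix.
#' @export
nonmax_suppress <- function(res, orientation, thetas = NULL) {
  if (inherits(orientation, "crf_response")) {
    thetas <- orientation$thetas
    orientation <- orientation$argmax
  }
  if (is.null(thetas)) stop("thetas must be supplied with an index matrix")
  stopifnot(identical(dim(res), dim(orientation)))
  h <- nrow(res); w <- ncol(res)
  # quantize the derivative-axis angle to an 8-neighbor step
  ang <- thetas[orientation] %% pi
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4   # 0:E, 1:SE, 2:S, 3:SW
  steps <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  shift0 <- function(dr, dc) {
    # res shifted so entry (i,j) holds res[i+dr, j+dc], zero outside
    out <- matrix(0, h, w)
    ri <- seq_len(h); ci <- seq_len(w)
    out[ri[ri + dr >= 1L & ri + dr <= h], ci[ci + dc >= 1L & ci + dc <= w]] <-
      res[ri[ri + dr >= 1L & ri + dr <= h] + dr, ci[ci + dc >= 1L & ci + dc <= w] + dc]
    out
  }
  keep <- matrix(FALSE, h, w)
  for (b in 0:3) {
    s <- steps[[b + 1L]]
    prv <- shift0(-s[1L], -s[2L])
    nxt <- shift0(s[1L], s[2L])
    keep_b <- res > prv & res >= nxt & res > 0
    sel <- bin == b
    keep[sel] <- keep_b[sel]
  }
  out <- res
  out[!keep] <- 0
  out
}

#' Hysteresis thresholding of a thinned response
#'
#' The high threshold is set so that a fraction `p` of the nonzero
#' candidate pixels reaches it (`p = 1` keeps every candidate); the low
#' threshold is `low_ratio` times the high one. Pixels at or above the
#' high threshold seed 8-connected growth through pixels at or above the
#' low threshold.
#'
#' @param thinned thinned response matrix (output of
#'   [nonmax_suppress()]).
#' @param p fraction of candidates retained, in (0, 1\]; default 1.
#' @param low_ratio low/high threshold ratio; default 0.4.
#' @return binary 0/1 integer matrix (an edge map).
#' @export
hysteresis <- function(thinned, p = 1, low_ratio = 0.4) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  h <- nrow(thinned); w <- ncol(thinned)
  nz <- thinned[thinned > 0]
  out <- matrix(0L, h, w)
  if (length(nz) == 0L) return(out)
  high <- stats::quantile(nz, 1 - p, type = 1, names = FALSE)
  low <- low_ratio * high
  strong <- thinned >= high
  weak <- thinned > 0 & thinned >= low
  visited <- strong
  frontier <- strong
  repeat {
    grown <- matrix(FALSE, h, w)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ri <- seq_len(h); ci <- seq_len(w)
      rs <- ri[ri + dr >= 1L & ri + dr <= h]
      cs <- ci[ci + dc >= 1L & ci + dc <= w]
      grown[rs, cs] <- grown[rs, cs] | frontier[rs + dr, cs + dc]
    }
    frontier <- grown & weak & !visited
    if (!any(frontier)) break
    visited <- visited | frontier
  }
  out[visited] <- 1L
  out
}

#' Precision / recall / F of a predicted edge map
#'
#' Predicted and ground-truth edge pixels are matched one-to-one,
#' greedily in order of increasing Euclidean distance, up to a distance
#' `tolerance`. Precision is the matched fraction of predicted pixels,
#' recall the matched fraction of ground-truth pixels, and
#' `F = 2PR / (P + R)` (0 when both are 0). When one side is empty its
#' own ratio defaults to 1 (both empty gives P = R = F = 1).
#'
#' @param pred,gt binary 0/1 matrices of the same shape.
#' @param tolerance maximum match distance in pixels; default 2.
#' @return an `edge_eval` list: `precision`, `recall`, `f_score`,
#'   `matched`, `n_pred`, `n_gt`, `tolerance`.
#' @export
evaluate_edges <- function(pred, gt, tolerance = 2) {
  stopifnot(identical(dim(pred), dim(gt)))
  pp <- which(pred != 0, arr.ind = TRUE)
  gp <- which(gt != 0, arr.ind = TRUE)
  np <- nrow(pp); ng <- nrow(gp)
  matched <- 0L
  if (np > 0L && ng > 0L) {
    d2 <- outer(pp[, 1L], gp[, 1L], "-")^2 + outer(pp[, 2L], gp[, 2L], "-")^2
    cand <- which(d2 <= tolerance^2, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      ord <- order(d2[cand], cand[, 1L], cand[, 2L])
      cand <- cand[ord, , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE; used_g[j] <- TRUE
          matched <- matched + 1L
        }
      }
    }
  }
  precision <- if (np == 0L) 1 else matched / np
  recall <- if (ng == 0L) 1 else matched / ng
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f_score = f,
                 matched = matched, n_pred = np, n_gt = ng,
                 tolerance = tolerance),
            class = "edge_eval")
}
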