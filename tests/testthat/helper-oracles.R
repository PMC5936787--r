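# Independent brute-force oracles. Everything here is written as literal
# loops over definitions, sharing no machinery with the package internals,
# so agreement is evidence the vectorized paths implement the formulas.

o_mirror <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i          # reflect about 0.5 (edge repeated)
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

o_correlate2 <- function(img, kern) {
  h <- nrow(img); w <- ncol(img)
  rh <- (nrow(kern) - 1) / 2; rw <- (ncol(kern) - 1) / 2
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in seq_len(nrow(kern))) for (b in seq_len(ncol(kern))) {
      ii <- o_mirror(i + a - rh - 1, h)
      jj <- o_mirror(j + b - rw - 1, w)
      s <- s + kern[a, b] * img[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# surround similarity sum, quadruple loop over pixels and kernel offsets
o_scalar_cue_weight <- function(cue, sigma_cue, wd) {
  h <- nrow(cue); w <- ncol(cue)
  r <- (nrow(wd) - 1) / 2
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in seq_len(nrow(wd))) for (b in seq_len(ncol(wd))) {
      if (wd[a, b] == 0) next
      ii <- o_mirror(i + a - r - 1, h)
      jj <- o_mirror(j + b - r - 1, w)
      s <- s + wd[a, b] * exp(-(cue[i, j] - cue[ii, jj])^2 / (2 * sigma_cue^2))
    }
    out[i, j] <- s
  }
  out
}

o_combine <- function(wt, wl, wc, E1, E2) {
  nrm <- function(E) {
    if (max(E) == min(E)) return(E * 0)
    (E - min(E)) / (max(E) - min(E))
  }
  n1 <- nrm(E1); n2 <- nrm(E2)
  out <- wt
  for (i in seq_len(nrow(wt))) for (j in seq_len(ncol(wt))) {
    out[i, j] <- if (n1[i, j] - n2[i, j] > 0)
      max(wt[i, j], wl[i, j], wc[i, j])
    else min(wt[i, j], wl[i, j], wc[i, j])
  }
  out
}

# literal two-stage stencil evaluation for two-direction sampling on a
# field known at odd rows/columns (plus the final row/column)
o_reconstruct_xy <- function(field) {
  h <- nrow(field); w <- ncol(field)
  srow <- function(i) i %% 2 == 1 || i == h
  scol <- function(j) j %% 2 == 1 || j == w
  out <- field
  for (i in 1:h) for (j in 1:w) {        # stage 1
    if (srow(i) && !scol(j)) out[i, j] <- 2 / 3 * field[i, j - 1] + 1 / 3 * field[i, j + 1]
    if (!srow(i) && scol(j)) out[i, j] <- 2 / 3 * field[i - 1, j] + 1 / 3 * field[i + 1, j]
  }
  out2 <- out
  for (i in 1:h) for (j in 1:w) {        # stage 2
    if (!srow(i) && !scol(j))
      out2[i, j] <- 1 / 3 * out[i - 1, j] + 1 / 3 * out[i, j - 1] +
        1 / 6 * out[i + 1, j] + 1 / 6 * out[i, j + 1]
  }
  out2
}

o_reconstruct_1d <- function(field, along = "x") {
  h <- nrow(field); w <- ncol(field)
  out <- field
  if (along == "x") {
    for (j in 1:w) if (j %% 2 == 0 && j != w)
      out[, j] <- 2 / 3 * field[, j - 1] + 1 / 3 * field[, j + 1]
  } else {
    for (i in 1:h) if (i %% 2 == 0 && i != h)
      out[i, ] <- 2 / 3 * field[i - 1, ] + 1 / 3 * field[i + 1, ]
  }
  out
}

# straight-line reimplementation of the whole inhibited-response pipeline
# (filter bank through half-wave rectified suppression), per-pixel surround
# sums, no shared package internals beyond the kernel constructors
o_monolithic_res <- function(img, sigma = 1, n_theta = 4, window_size = 5,
                             alpha = 5, sdt = 0.2, sdl = 0.05, sdc = 0.05,
                             outer_factor = 4) {
  h <- nrow(img); w <- ncol(img)
  side <- ceiling(8 * sigma); if (side %% 2 == 0) side <- side + 1
  r <- (side - 1) / 2
  mk_deriv <- function(theta, sg) {
    s <- ceiling(8 * sg); if (s %% 2 == 0) s <- s + 1
    rr <- (s - 1) / 2
    k <- matrix(0, s, s)
    for (a in 1:s) for (b in 1:s) {
      y <- a - rr - 1; x <- b - rr - 1
      xt <- x * cos(theta) + y * sin(theta)
      yt <- -x * sin(theta) + y * cos(theta)
      k[a, b] <- -(xt / sg^2) * exp(-(xt^2 + yt^2) / (2 * sg^2)) / (2 * pi * sg^2)
    }
    k
  }
  bank <- function(sg) {
    es <- array(0, c(h, w, n_theta))
    for (i in 1:n_theta)
      es[, , i] <- abs(o_correlate2(img, mk_deriv((i - 1) * pi / n_theta, sg)))
    es
  }
  e1 <- bank(sigma); e2 <- bank(2 * sigma)
  E1 <- apply(e1, c(1, 2), max); E2 <- apply(e2, c(1, 2), max)
  # raised cosine window cues
  wr <- (window_size - 1) / 2; R <- window_size / 2
  ww <- matrix(0, window_size, window_size)
  for (a in 1:window_size) for (b in 1:window_size) {
    d <- sqrt((a - wr - 1)^2 + (b - wr - 1)^2)
    if (d <= R) ww[a, b] <- 0.5 * (1 + cos(pi * d / R))
  }
  mu <- sum(ww)
  L <- o_correlate2(img, ww / mu)
  C <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    s <- 0
    for (a in 1:window_size) for (b in 1:window_size) {
      ii <- o_mirror(i + a - wr - 1, h); jj <- o_mirror(j + b - wr - 1, w)
      s <- s + ww[a, b] * (img[ii, jj] - L[i, j])^2
    }
    C[i, j] <- (s / mu) / (L[i, j]^2 + 1e-6)
  }
  # distance kernel
  so <- outer_factor * sigma
  rd <- ceiling(4 * so); sided <- 2 * rd + 1
  wd <- matrix(0, sided, sided)
  for (a in 1:sided) for (b in 1:sided) {
    d2 <- (a - rd - 1)^2 + (b - rd - 1)^2
    v <- exp(-d2 / (2 * so^2)) / (2 * pi * so^2) -
      exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
    wd[a, b] <- max(v, 0)
  }
  wd <- wd / sum(wd)
  # center orientation average (Gaussian smoothing of each component)
  gside <- ceiling(8 * sigma); if (gside %% 2 == 0) gside <- gside + 1
  gr <- (gside - 1) / 2
  gk <- matrix(0, gside, gside)
  for (a in 1:gside) for (b in 1:gside)
    gk[a, b] <- exp(-((a - gr - 1)^2 + (b - gr - 1)^2) / (2 * sigma^2))
  gk <- gk / sum(gk)
  tcrf <- array(0, c(h, w, n_theta))
  tncrf <- array(0, c(h, w, n_theta))
  for (q in 1:n_theta) {
    tcrf[, , q] <- o_correlate2(e1[, , q], gk)
    tncrf[, , q] <- o_correlate2(e1[, , q], wd)
  }
  WT <- matrix(0, h, w); WL <- matrix(0, h, w); WC <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    WT[i, j] <- exp(-sum((tcrf[i, j, ] - tncrf[i, j, ])^2) / (2 * sdt^2))
  }
  WL <- o_scalar_cue_weight(L, sdl, wd)
  WC <- o_scalar_cue_weight(C, sdc, wd)
  wcom <- o_combine(WT, WL, WC, E1, E2)
  inhib <- o_correlate2(E1, wd)
  res <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    z <- E1[i, j] - alpha * wcom[i, j] * inhib[i, j]
    res[i, j] <- if (z < 0) 0 else z
  }
  res
}
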