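# Surround inhibition: distance kernel, per-cue weights, scale-guided
# fusion, and half-wave-rectified suppression.

test_that("distance kernel is a normalized annulus with decaying tail", {
  k <- distance_kernel(1.5)
  ctr <- (nrow(k$w_d) + 1) / 2
  expect_identical(k$w_d[ctr, ctr], 0)
  expect_true(all(k$w_d >= 0))
  expect_lt(abs(sum(k$w_d) - 1), 1e-10)
  # radial profile decreases monotonically beyond the annulus peak
  prof <- k$w_d[ctr, ctr:ncol(k$w_d)]
  pk <- which.max(prof)
  expect_true(all(diff(prof[pk:length(prof)]) <= 1e-15))
  expect_error(distance_kernel(0), "positive")
})

test_that("orientation weight is the Gaussian similarity of the vector fields", {
  f <- array(runif(6 * 6 * 4), c(6, 6, 4))
  expect_equal(orientation_weight(f, f), matrix(1, 6, 6))

  # one pixel differing by norm d -> exp(-d^2 / (2 * 0.2^2)) there
  g <- f
  g[3, 4, ] <- g[3, 4, ] + c(0.1, 0, -0.1, 0.05)
  d2 <- sum(c(0.1, 0, -0.1, 0.05)^2)
  wt <- orientation_weight(f, g, sigma_dtheta = 0.2)
  expect_equal(wt[3, 4], exp(-d2 / (2 * 0.2^2)), tolerance = 1e-12)

  # random fields: per-pixel scalar-loop oracle
  set.seed(17)
  a <- array(runif(5 * 5 * 3), c(5, 5, 3))
  b <- array(runif(5 * 5 * 3), c(5, 5, 3))
  w <- orientation_weight(a, b, 0.3)
  for (i in 1:5) for (j in 1:5)
    expect_equal(w[i, j], exp(-sum((a[i, j, ] - b[i, j, ])^2) / (2 * 0.09)),
                 tolerance = 1e-12)
  expect_error(orientation_weight(a, b[1:4, , , drop = FALSE]), "dimensions")
})

test_that("scalar cue weight matches the quadruple-loop surround oracle", {
  k <- distance_kernel(0.5)
  cm <- matrix(0.42, 7, 7)
  expect_equal(scalar_cue_weight(cm, 0.05, k), matrix(1, 7, 7),
               tolerance = 1e-12)

  # center value far from every surround value -> weight ~ 0 (image large
  # enough that no mirrored copy of the center falls inside the surround)
  far <- matrix(0, 19, 19); far[10, 10] <- 1
  expect_lt(scalar_cue_weight(far, 0.01, k)[10, 10], 1e-12)

  set.seed(23)
  cue <- matrix(runif(7 * 7), 7)
  expect_equal(scalar_cue_weight(cue, 0.05, k),
               o_scalar_cue_weight(cue, 0.05, k$w_d), tolerance = 1e-8)
  expect_true(all(scalar_cue_weight(cue, 0.05, k) <= 1 + 1e-12))
})

test_that("scale-guided combination takes max on fine-dominant pixels, min elsewhere", {
  set.seed(29)
  wt <- matrix(runif(36), 6); wl <- matrix(runif(36), 6); wc <- matrix(runif(36), 6)
  E1 <- matrix(runif(36), 6); E2 <- matrix(runif(36), 6)
  expect_equal(combine_weights(wt, wt, wt, E1, E2), wt)
  expect_equal(combine_weights(wt, wl, wc, E1, E2),
               o_combine(wt, wl, wc, E1, E2), tolerance = 1e-12)

  # equal normalized responses take the min branch
  expect_equal(combine_weights(wt, wl, wc, E1, E1), pmin(wt, wl, wc))
  # degenerate constant response maps normalize to zero -> min branch
  expect_equal(combine_weights(wt, wl, wc, matrix(1, 6, 6), matrix(2, 6, 6)),
               pmin(wt, wl, wc))
})

test_that("suppression is bounded, rectified and monotone in alpha", {
  set.seed(31)
  img <- matrix(runif(20 * 20), 20)
  st <- orientation_responses(img, 1, 4)
  E <- crf_response(st)$E
  k <- distance_kernel(1)
  w1 <- matrix(runif(400), 20)

  expect_equal(suppress(E, w1, k, alpha = 0), E)
  expect_equal(suppress(E, matrix(0, 20, 20), k, alpha = 5), E)

  r2 <- suppress(E, w1, k, 2)
  r5 <- suppress(E, w1, k, 5)
  expect_true(all(r5 >= 0))
  expect_true(all(r5 <= E + 1e-15))
  expect_true(all(r5 <= r2 + 1e-15))   # monotone non-increasing in alpha
  expect_error(suppress(E, w1, k, -1), "nonnegative")
})

test_that("an edge inside dense texture is suppressed more than a clean edge", {
  clean <- generate_scene("step-edge", 48, texture_density = 0, seed = 4)
  noisy <- generate_scene("step-edge", 48, texture_density = 0.6, seed = 4)
  cfg <- smci_config()
  dc <- smci_detect(clean$image, cfg, mode = "mci", sparse = FALSE)
  dn <- smci_detect(noisy$image, cfg, mode = "mci", sparse = FALSE)
  edge <- clean$contour_mask == 1
  expect_gt(mean(dc$res[edge]), mean(dn$res[edge]))
})

test_that("modular pipeline equals the monolithic straight-line reimplementation", {
  set.seed(37)
  img <- matrix(runif(32 * 32), 32)
  cfg <- smci_config(sigma = 1, n_theta = 4, window_size = 5)
  d <- smci_detect(img, cfg, mode = "mci", sparse = FALSE)
  oracle <- o_monolithic_res(img, sigma = 1, n_theta = 4, window_size = 5)
  expect_equal(d$res, oracle, tolerance = 1e-8)
})

test_that("a constant image yields an all-zero response end to end", {
  d <- smci_detect(matrix(0.5, 40, 40), mode = "mci")
  expect_lt(max(d$res), 1e-10)
  expect_lt(max(d$final), 1e-10)
  expect_identical(sum(d$binary), 0L)
})
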