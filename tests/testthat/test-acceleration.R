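# Acceleration: prior filtering, uniform sampling, stencil reconstruction,
# and the instrumented work-reduction counter.

test_that("prior mask thresholds against the global maximum response", {
  set.seed(41)
  E <- matrix(runif(64), 8)
  expect_true(all(prior_mask(E, 0) == 1L))
  m1 <- prior_mask(E, 1)
  expect_identical(which(m1 == 1L), which(E == max(E)))
  m <- prior_mask(E, 0.3)
  for (i in 1:8) for (j in 1:8)
    expect_identical(m[i, j], as.integer(E[i, j] >= 0.3 * max(E)))
  expect_error(prior_mask(E, 1.2), "fraction")
})

test_that("sampled positions cover the stride grid plus boundaries", {
  s <- sampled_positions(c(6, 6), "none")
  expect_true(all(s))
  sx <- sampled_positions(c(6, 6), "x")
  expect_true(all(sx[, c(1, 3, 5, 6)]))
  expect_true(!any(sx[, c(2, 4)]))
  sxy <- sampled_positions(c(4, 4), "xy")
  # four interior-stencil sample points on a 4x4 grid (plus the always-
  # sampled final row/column)
  expect_true(all(sxy[c(1, 3), c(1, 3)]))
  expect_false(sxy[2, 2])
  expect_lte(sum(sxy), 16)
  expect_error(sampled_positions(c(6, 6), "x", stride = 3), "stride")
})

test_that("reconstruction stencils conserve constants and reproduce the
           printed indicator expansion", {
  for (mode in c("x", "y", "xy")) {
    f <- matrix(NA_real_, 7, 8)
    f[sampled_positions(c(7, 8), mode)] <- 0.37
    expect_equal(reconstruct_field(f, mode), matrix(0.37, 7, 8),
                 tolerance = 1e-12)
  }
  # indicator at the first sampled point
  f <- matrix(NA_real_, 6, 6)
  s <- sampled_positions(c(6, 6), "xy")
  f[s] <- 0; f[1, 1] <- 1
  r <- reconstruct_field(f, "xy")
  expect_equal(r[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(r[2, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(r[2, 2], 4 / 9, tolerance = 1e-12)
  expect_equal(r[2, 3], 0, tolerance = 1e-12)  # off the indicator's stencils

  bad <- matrix(NA_real_, 6, 6)
  expect_error(reconstruct_field(bad, "x"), "missing")
})

test_that("reconstruction agrees with the literal two-stage loop oracle", {
  set.seed(43)
  for (dims in list(c(5, 5), c(8, 11), c(12, 12))) {
    full <- matrix(runif(prod(dims)), dims[1])
    for (mode in c("x", "y", "xy")) {
      f <- full
      f[!sampled_positions(dims, mode)] <- NA
      got <- reconstruct_field(f, mode)
      ora <- switch(mode,
                    x = o_reconstruct_1d(full, "x"),
                    y = o_reconstruct_1d(full, "y"),
                    xy = o_reconstruct_xy(full))
      expect_equal(got, ora, tolerance = 1e-12)
      # reconstructed values stay within the range of the samples
      expect_true(all(got >= min(full[!is.na(f)]) - 1e-12))
      expect_true(all(got <= max(full[!is.na(f)]) + 1e-12))
    }
  }
})

test_that("masked and sampled weights agree with the full field where computed", {
  set.seed(47)
  img <- matrix(runif(24 * 24), 24)
  cfg <- smci_config(sigma = 1, n_theta = 4, window_size = 5)
  st <- orientation_responses(img, cfg$sigma, cfg$n_theta)
  E <- crf_response(st)$E
  win <- raised_cosine_window(cfg$window_size)
  L <- luminance_map(img, win)
  C <- contrast_map(img, L, win)
  k <- distance_kernel(cfg$sigma)

  full <- inhibition_weights(st, L, C, E, k, cfg)
  expect_identical(full$n_evaluated, 24L * 24L)

  # prior filtering: computed pixels bitwise identical, masked pixels 1
  half <- inhibition_weights(st, L, C, E, k, cfg, prior_fraction = 0.3)
  mask <- prior_mask(E, 0.3) == 1L
  for (fld in c("w_theta", "w_l", "w_c")) {
    expect_identical(half[[fld]][mask], full[[fld]][mask])
    expect_true(all(half[[fld]][!mask] == 1))
  }
  expect_identical(half$n_evaluated, sum(mask))

  # sampling: computed at sampled positions bitwise, stencils elsewhere
  sx <- inhibition_weights(st, L, C, E, k, cfg, sampling = "x")
  samp <- sampled_positions(c(24, 24), "x")
  expect_identical(sx$w_l[samp], full$w_l[samp])
  expect_equal(sx$w_l, reconstruct_field(ifelse(samp, full$w_l, NA), "x"),
               tolerance = 1e-12)
  expect_identical(sx$n_evaluated, sum(samp))
})

test_that("work reduction: combined mode evaluates far fewer weights", {
  for (kind in c("step-edge", "disc-on-texture", "bar-in-clutter")) {
    sc <- generate_scene(kind, 48, seed = 7)
    d_full <- smci_detect(sc$image, mode = "mci", sparse = FALSE)
    d_prior <- smci_detect(sc$image, mode = "prior", sparse = FALSE)
    d_comb <- smci_detect(sc$image, mode = "combined", sparse = FALSE)
    expect_identical(d_full$weight_evals, d_full$n_pixels)
    # one-direction sampling alone computes about half the columns
    expect_lte(smci_detect(sc$image, mode = "sample-x",
                           sparse = FALSE)$weight_evals,
               ceiling(48 / 2 + 1) * 48)
    # combined evaluates strictly fewer than prior-only at equal mask
    d_prior10 <- smci_detect(sc$image, mode = "prior", prior_fraction = 0.1,
                             sparse = FALSE)
    expect_lt(d_comb$weight_evals, d_prior10$weight_evals)
    expect_lt(d_comb$weight_evals, d_full$weight_evals)
  }
})
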