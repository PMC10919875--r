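test_that("PCA recovers low-rank structure and the complete basis", {
  set.seed(21)
  t <- seq(0, 2 * pi, length.out = 60)
  basis <- rbind(sin(t), cos(2 * t))
  w <- matrix(rnorm(200 * 2), 200, 2)
  x <- w %*% basis  # exact rank 2

  st2 <- fit_pca(x, 2)
  expect_equal(sum(st2$explained_ratio), 1, tolerance = 1e-9)

  # full-rank data with a complete basis explains everything
  xf <- matrix(rnorm(50 * 10), 50, 10)
  stf <- fit_pca(xf, 10)
  expect_equal(sum(stf$explained_ratio), 1, tolerance = 1e-9)

  expect_error(fit_pca(xf, 50), "too large")
  expect_error(fit_pca(xf, 0), "at least 1")

  # ratios are non-increasing and total 1 over all components
  expect_true(all(diff(stf$all_ratios) <= 1e-12))
  expect_equal(sum(stf$all_ratios), 1, tolerance = 1e-9)
  # components are orthonormal
  expect_equal(st2$components %*% t(st2$components), diag(2),
               tolerance = 1e-9)
})

test_that("PCA transform and inverse behave like an orthogonal projection", {
  set.seed(22)
  x <- matrix(rnorm(300 * 40), 300, 40) %*% matrix(rnorm(40 * 40), 40, 40)
  st <- fit_pca(x, 5)

  # the fitted mean maps to the zero loading vector
  expect_equal(as.numeric(pca_transform(st$center, st)), rep(0, 5),
               tolerance = 1e-9)
  # mean + first component maps to the first basis vector
  expect_equal(as.numeric(pca_transform(st$center + st$components[1, ], st)),
               c(1, 0, 0, 0, 0), tolerance = 1e-9)
  # zero loadings reconstruct the mean
  expect_equal(as.numeric(pca_inverse(rep(0, 5), st)), st$center,
               tolerance = 1e-12)

  # in-span data round-trips exactly
  span <- pca_inverse(pca_transform(x[1:20, ], st), st)
  span2 <- pca_inverse(pca_transform(span, st), st)
  expect_equal(span, span2, tolerance = 1e-9)

  # reconstruction residual decreases in k and matches discarded variance
  resid_k <- vapply(c(2, 5, 10, 20), function(k) {
    stk <- fit_pca(x, k)
    mean(rowSums((x - pca_inverse(pca_transform(x, stk), stk))^2))
  }, numeric(1))
  expect_true(all(diff(resid_k) < 0))
  st20 <- fit_pca(x, 20)
  discarded <- (1 - sum(st20$explained_ratio)) * st20$total_variance
  n <- nrow(x)
  expect_equal(resid_k[4], discarded * (n - 1) / n, tolerance = 1e-6)

  expect_error(pca_transform(matrix(0, 2, 7), st), "length 40")
})

test_that("peak features find extrema with earliest-time tie-breaking", {
  # 10 Hz sine on [0, 100] ms: max 1 at 25 ms, min -1 at 75 ms
  g <- time_grid(0, 100, 0.5)
  t <- grid_times(g)
  w <- waveform(sin(2 * pi * 10 * t / 1000), g)
  pf <- peak_features(w)
  expect_equal(unname(pf), c(1, 25, -1, 75), tolerance = 1e-6)

  # constant waveform: both extrema at the first sample
  pc <- peak_features(waveform(rep(2.5, g$n), g))
  expect_equal(unname(pc), c(2.5, 0, 2.5, 0))

  # RC exemplar: trough of the net -0.2 mA pulse at pulse offset
  v <- simulate_rc(0.1, 0.3, 0, time_grid())
  pv <- peak_features(v)
  expect_equal(unname(pv["min"]), -0.2 * (1 - exp(-20 / 6)), tolerance = 1e-9)
  expect_equal(unname(pv["t_min"]), 100)

  # appending flat baseline between the extrema's values changes nothing
  g2 <- time_grid(0, 150, 0.5)
  t2 <- grid_times(g2)
  w2 <- c(sin(2 * pi * 10 * t / 1000), rep(0, g2$n - g$n))
  expect_equal(unname(peak_features(w2, times = t2))[1:4], c(1, 25, -1, 75),
               tolerance = 1e-6)

  expect_error(peak_features(numeric(0), times = numeric(0)), "non-empty")
})

test_that("band power separates canonical frequency bands", {
  g <- time_grid(0, 2000, 0.5)  # 2 s window, fs = 2 kHz
  t <- grid_times(g)

  expect_equal(unname(band_power(waveform(rep(0, g$n), g))), rep(0, 4))

  bp20 <- band_power(waveform(sin(2 * pi * 20 * t / 1000), g))
  expect_gt(bp20[2] / sum(bp20), 0.99)  # 20 Hz lands in 13-30

  bp60 <- band_power(waveform(sin(2 * pi * 60 * t / 1000), g))
  expect_equal(unname(which.max(bp60)), 4)  # 60 Hz lands in 50-80

  # band total cannot exceed the full periodogram power (Parseval)
  x <- rnorm(g$n)
  total <- mean(x^2)  # time-domain power
  expect_lte(sum(band_power(x, dt = 0.5)), total + 1e-9)

  # grids that cannot resolve 80 Hz are rejected
  expect_error(band_power(rnorm(11), dt = 10), "too coarse")
  expect_error(summary_bandpower(time_grid(0, 100, 10)), "too coarse")
})

test_that("observation noise has the requested moments and is reproducible", {
  x <- matrix(0, 1000, 1000)
  expect_identical(add_observation_noise(x, 0, seed = 1), x)

  y <- add_observation_noise(x, 0.01, seed = 2)
  expect_lt(abs(mean((y - x)^2) - 0.01), 5e-4)
  expect_lt(abs(mean(y - x)), 1e-3)

  expect_identical(add_observation_noise(x, 0.01, seed = 2), y)
  expect_false(identical(add_observation_noise(x, 0.01, seed = 3), y))
  expect_error(add_observation_noise(x, -1), "non-negative")
})

test_that("summary transforms apply uniformly through the common interface", {
  g <- time_grid(0, 200, 0.5)
  sim <- rc_simulator(g)
  th <- cbind(runif(30), runif(30), runif(30, -50, 50))
  x <- simulate_batch(sim, th)

  idt <- summary_identity(g)
  expect_equal(apply_summary(idt, x), x)
  expect_equal(idt$m, g$n)

  pk <- summary_peak(g)
  sp <- apply_summary(pk, x)
  expect_equal(dim(sp), c(30L, 4L))
  expect_equal(sp[3, ], peak_features(x[3, ], times = grid_times(g)))

  bp <- summary_bandpower(g)
  sb <- apply_summary(bp, x)
  expect_equal(dim(sb), c(30L, 4L))
  expect_true(all(sb >= 0))

  st <- fit_pca(x, 3, grid = g)
  expect_equal(apply_summary(st, x), pca_transform(x, st))
})
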