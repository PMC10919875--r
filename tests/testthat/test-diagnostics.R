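test_that("parameter recovery error matches hand-computed cases and bounds", {
  # worked example: samples {0.2, 0.4} against truth 0.3
  expect_equal(parameter_recovery_error(matrix(c(0.2, 0.4), 2, 1), 0.3),
               0.1, ignore_attr = TRUE)
  # degenerate posterior at the truth: perfect recovery
  expect_equal(parameter_recovery_error(matrix(0.3, 100, 1), 0.3), 0,
               ignore_attr = TRUE)
  # degenerate posterior at the opposite corner: worst recovery
  expect_equal(parameter_recovery_error(matrix(1, 100, 1), 0), 1,
               ignore_attr = TRUE)
  # squared variant
  expect_equal(parameter_recovery_error(matrix(c(0.2, 0.4), 2, 1), 0.3,
                                        squared = TRUE),
               0.01, ignore_attr = TRUE)
  # multi-parameter: one value per column, in [0, 1]
  set.seed(31)
  s <- matrix(runif(300), 100, 3)
  pre <- parameter_recovery_error(s, c(0.2, 0.5, 0.9))
  expect_length(pre, 3)
  expect_true(all(pre >= 0 & pre <= 1))
  expect_error(parameter_recovery_error(matrix(numeric(0), 0, 1), 0.5),
               "at least one")
  expect_error(parameter_recovery_error(matrix(1.7, 5, 1), 0.5),
               "unit-space")
})

test_that("posterior predictive check is the mean Euclidean residual", {
  x0 <- c(1, 2, 3, 4, 5)
  expect_equal(posterior_predictive_check(rbind(x0, x0, x0), x0), 0)
  d1 <- x0; d1[1:2] <- d1[1:2] + c(3, 4)
  expect_equal(posterior_predictive_check(rbind(d1), x0), 5)
  # two draws at distances 1 and 3 average to 2
  da <- x0; da[1] <- da[1] + 1
  db <- x0; db[1] <- db[1] + 3
  expect_equal(posterior_predictive_check(rbind(da, db), x0), 2)
  # per-sample normalization
  expect_equal(posterior_predictive_check(rbind(d1), x0, per_sample = TRUE),
               5 / sqrt(5))
  expect_error(posterior_predictive_check(matrix(0, 2, 3), x0), "samples")
})

test_that("overlap coefficient hits its endpoints and the Gaussian closed form", {
  # identical densities overlap completely
  f <- function(u) dnorm(u[, 1], 0.5, 0.1)
  expect_equal(overlap_from_densities(f, f, 1, 1), 1, tolerance = 1e-9)

  # disjoint uniform boxes do not overlap
  f0 <- function(u) as.numeric(u[, 1] > 0 & u[, 1] < 0.4)
  f1 <- function(u) as.numeric(u[, 1] > 0.6 & u[, 1] < 1.0)
  expect_equal(overlap_from_densities(f0, f1, 1, 1), 0)

  # equal-sd Gaussians at 2-sigma separation: OVL = 2 * pnorm(-1)
  sg <- 0.08
  g0 <- function(u) dnorm(u[, 1], 0.42, sg)
  g1 <- function(u) dnorm(u[, 1], 0.42 + 2 * sg, sg)
  ovl <- overlap_from_densities(g0, g1, 1, 1)
  expect_lt(abs(ovl - 2 * pnorm(-1)), 0.01)
  # symmetry
  expect_equal(overlap_from_densities(g1, g0, 1, 1), ovl, tolerance = 1e-12)

  # multivariate marginalization: product density, overlap on one margin
  h0 <- function(u) dnorm(u[, 1], 0.42, sg) * dnorm(u[, 2], 0.5, 0.1)
  h1 <- function(u) dnorm(u[, 1], 0.42 + 2 * sg, sg) * dnorm(u[, 2], 0.5, 0.1)
  expect_lt(abs(overlap_from_densities(h0, h1, 2, 1) - 2 * pnorm(-1)), 0.01)
  expect_equal(overlap_from_densities(h0, h1, 2, 2), 1, tolerance = 1e-6)

  # tensor grids are refused in high dimension
  expect_error(overlap_from_densities(f, f, 5, 1), "overlap_from_samples")
})

test_that("grid OVL and the sample-KDE fallback agree on Gaussian mocks", {
  sg <- 0.08
  g0 <- function(u) dnorm(u[, 1], 0.42, sg)
  g1 <- function(u) dnorm(u[, 1], 0.42 + 2 * sg, sg)
  grid_val <- overlap_from_densities(g0, g1, 1, 1)
  set.seed(41)
  s0 <- matrix(rnorm(20000, 0.42, sg), ncol = 1)
  s1 <- matrix(rnorm(20000, 0.42 + 2 * sg, sg), ncol = 1)
  kde_val <- overlap_from_samples(s0, s1, 1)
  expect_lt(abs(grid_val - kde_val), 0.05)
})

test_that("posterior correlation reports Pearson r with p-value", {
  s <- cbind(1:50, 2 * (1:50) + 3)
  ct <- posterior_correlation(s, 1, 2)
  expect_equal(ct$estimate, 1)
  expect_true(ct$defined)

  set.seed(42)
  null <- matrix(runif(2e4), 1e4, 2)
  expect_lt(abs(posterior_correlation(null, 1, 2)$estimate), 0.05)

  flat <- cbind(rep(1, 10), rnorm(10))
  ctf <- posterior_correlation(flat, 1, 2)
  expect_false(ctf$defined)
  expect_true(is.na(ctf$estimate))
  expect_error(posterior_correlation(matrix(0, 2, 2), 1, 2), "3 samples")
})

test_that("pair-plot export carries densities and scatter panels", {
  set.seed(43)
  s <- matrix(runif(3000), 1000, 3)
  pp <- pairplot_export(s, c("a", "b", "c"))
  expect_length(pp$densities, 3)
  expect_length(pp$scatter, 3)  # d(d-1)/2 panels
  for (d in pp$densities) {
    integral <- sum(d$density) * diff(d$x[1:2])
    expect_lt(abs(integral - 1), 0.01)
    expect_true(all(d$density >= 0))
  }
  pp1 <- pairplot_export(matrix(rnorm(500), ncol = 1))
  expect_length(pp1$densities, 1)
  expect_length(pp1$scatter, 0)
})

test_that("the diagnostic grid lays out PRE and PPC per grid point", {
  # small 2-parameter toy: waveform (theta1, theta2) observed with noise
  sim2 <- simulator("toy2", c("a", "b"), time_grid(0, 1, 1),
                    function(th, seed) c(th[1], th[2]))
  pr2 <- prior_spec(data.frame(name = c("a", "b"), low = 0, high = 1,
                               transform = "linear"))
  ds <- generate_dataset(sim2, pr2, "identity", 3000,
                         noise_variance = 0.005, seed = 55)
  post <- train_posterior(ds, seed = 56, max_epochs = 40, patience = 8)

  dg <- diagnostic_grid(post, sim2, resolution = 3, n_post_samples = 200,
                        n_ppc_sims = 20, seed = 57)
  expect_equal(nrow(dg), 9L)  # resolution^d
  expect_equal(sort(unique(dg$u_a)), seq(0.05, 0.95, length.out = 3))
  expect_true(all(c("pre_a", "pre_b", "ppc", "ok") %in% names(dg)))
  expect_true(all(dg$ok))
  expect_true(all(dg$ppc >= 0))
  expect_true(all(dg$pre_a >= 0 & dg$pre_a <= 1))
  # a well-trained toy posterior concentrates near the truth everywhere
  expect_lt(mean(dg$pre_a), 0.2)

  sl <- grid_slice(dg, "pre_a", c("a", "b"))
  expect_equal(dim(sl), c(3L, 3L))
  expect_equal(sl["0.05", "0.95"],
               mean(dg$pre_a[dg$u_a == 0.05 & dg$u_b == 0.95]))
  sl_max <- grid_slice(dg, "ppc", c(1, 2), reduce = "max")
  expect_equal(dim(sl_max), c(3L, 3L))
})
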