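test_that("input current places the two square pulses correctly", {
  g <- time_grid()
  t <- grid_times(g)

  # worked exemplar: positive pulse at 80 ms, negative at 117.5 ms
  ie <- rc_input_current(0.3, 0.5, 37.5, g)
  expect_equal(ie[t == 90], 0.3)
  expect_equal(ie[t == 120], -0.5)
  expect_equal(ie[t == 50], 0)
  expect_equal(ie[t == 110], 0)  # gap between the pulses

  # perfectly overlapping pulses sum to a single net pulse
  ie0 <- rc_input_current(0.1, 0.3, 0, g)
  expect_true(all(abs(ie0[t >= 80 & t < 100] - (-0.2)) < 1e-12))
  expect_true(all(ie0[t < 80 | t >= 100] == 0))

  # half-open windows: current off exactly at pulse offset
  expect_equal(ie0[t == 100], 0)

  # zero amplitudes give zero current for any latency
  expect_true(all(rc_input_current(0, 0, -40, g) == 0))

  # pulse window leaving the grid span is rejected with a bounds message
  expect_error(rc_input_current(0.1, 0.1, 160, g), "grid span")
  expect_error(rc_input_current(0.1, 0.1, -90, g), "grid span")
  expect_error(rc_input_current(-0.1, 0.1, 0, g), "i_pos")
})

test_that("voltage response matches the segment-stepping oracle on random draws", {
  g <- time_grid()
  pr <- prior_preset("rc_circuit")
  set.seed(404)
  u <- matrix(runif(100 * 3), 100, 3)
  theta <- unit_to_physical(u, pr)
  for (i in seq_len(nrow(theta))) {
    v <- simulate_rc(theta[i, 1], theta[i, 2], theta[i, 3], g)
    ref <- rc_oracle(theta[i, 1], theta[i, 2], theta[i, 3], g)
    expect_lt(max(abs(v - ref)) / max(max(abs(ref)), 1e-12), 1e-6)
  }
})

test_that("adaptive ODE integration agrees with the analytic fast path", {
  g <- time_grid()
  set.seed(405)
  for (i in 1:8) {
    th <- c(runif(1), runif(1), runif(1, -75, 75))
    va <- simulate_rc(th[1], th[2], th[3], g, method = "analytic")
    vo <- simulate_rc(th[1], th[2], th[3], g, method = "ode")
    expect_lt(max(abs(va - vo)) / max(max(abs(va)), 1e-12), 1e-6)
  }
})

test_that("step response and worked exemplars match closed forms", {
  # constant step from t = 0: V(tau) = R * I * (1 - exp(-1))
  g <- time_grid(0, 100, 0.5)
  v <- simulate_rc(0.5, 0, 0, g, onset = 0, duration = 50)
  expect_equal(v[grid_times(g) == 6], 0.5 * (1 - exp(-1)), tolerance = 1e-9)

  # net -0.2 mA pulse: trough at pulse offset
  g <- time_grid()
  v <- simulate_rc(0.1, 0.3, 0, g)
  expect_equal(v[grid_times(g) == 100], -0.2 * (1 - exp(-20 / 6)),
               tolerance = 1e-9)

  # zero input stays at equilibrium E = 0
  expect_true(all(simulate_rc(0, 0, 10, g) == 0))

  # non-finite parameters are rejected
  expect_error(simulate_rc(NaN, 0.1, 0, g), "finite")
})

test_that("the RC system is linear and degenerate at zero latency", {
  g <- time_grid()
  set.seed(406)
  for (i in 1:10) {
    th <- c(runif(1), runif(1), runif(1, -75, 75))
    full <- simulate_rc(th[1], th[2], th[3], g)
    pos_only <- simulate_rc(th[1], 0, 0, g)
    neg_only <- simulate_rc(0, th[2], th[3], g)
    expect_equal(as.numeric(full), as.numeric(pos_only + neg_only),
                 tolerance = 1e-10)
  }
  # latency 0: only the net amplitude i_pos - i_neg matters
  a <- simulate_rc(0.7, 0.9, 0, g)
  b <- simulate_rc(0.1, 0.3, 0, g)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-10)
})

test_that("batch simulation is deterministic and row-consistent", {
  sim <- rc_simulator()

  # empty batch keeps the output width
  empty <- simulate_batch(sim, matrix(numeric(0), 0, 3))
  expect_equal(dim(empty), c(0L, sim$grid$n))

  # identical rows give identical waveforms; single-call oracle bit-match
  th <- rbind(c(0.1, 0.3, 0), c(0.1, 0.3, 0), c(0.1, 0.3, 0))
  b <- simulate_batch(sim, th, seed = 5)
  expect_identical(b[1, ], b[2, ])
  expect_identical(b[1, ], as.numeric(simulate_rc(0.1, 0.3, 0, sim$grid)))

  # reruns with the same seed are bit-identical
  set.seed(77)
  th2 <- cbind(runif(20), runif(20), runif(20, -75, 75))
  expect_identical(simulate_batch(sim, th2, seed = 9),
                   simulate_batch(sim, th2, seed = 9))

  # column mismatch is a descriptive error
  expect_error(simulate_batch(sim, matrix(0.5, 2, 2)), "expects 3")
})

test_that("the simulator registry resolves plugins by name", {
  expect_true("rc_circuit" %in% simulator_registry())
  sim <- get_simulator("rc_circuit")
  expect_s3_class(sim, "sbi_simulator")
  expect_equal(sim$param_names, c("i_pos", "i_neg", "latency"))

  register_simulator("test_flatline", function(n_samples = 11) {
    simulator("test_flatline", "level", time_grid(0, n_samples - 1, 1),
              function(th, seed) rep(th[1], n_samples))
  })
  flat <- get_simulator("test_flatline", n_samples = 5)
  expect_equal(as.numeric(simulate_one(flat, 2.5)), rep(2.5, 5))
  expect_error(get_simulator("no_such_model"), "registered")
})
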