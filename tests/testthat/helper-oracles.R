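# Independent oracles and small fixtures shared across tests.

# Piecewise-exponential reference solution of C dV/dt = (E - V)/R + I(t)
# for piecewise-constant input: steps sequentially through the segments
# between input breakpoints, relaxing toward E + R*I with time constant
# tau on each. Deliberately structured differently from the package's
# superposition fast path.
rc_oracle <- function(i_pos, i_neg, latency, grid, C = 6, R = 1, E = 0,
                      onset = 80, duration = 20) {
  tau <- R * C
  t <- grid_times(grid)
  current_at <- function(tt) {
    i_pos * (tt >= onset & tt < onset + duration) -
      i_neg * (tt >= onset + latency & tt < onset + duration + latency)
  }
  edges <- sort(unique(c(grid$t_start, grid$t_stop,
                         onset, onset + duration,
                         onset + latency, onset + duration + latency)))
  edges <- edges[edges >= grid$t_start & edges <= grid$t_stop]
  v <- numeric(grid$n)
  v0 <- E
  for (s in seq_len(length(edges) - 1)) {
    a <- edges[s]; b <- edges[s + 1]
    I <- current_at((a + b) / 2)
    v_inf <- E + R * I
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    v[idx] <- v_inf + (v0 - v_inf) * exp(-(t[idx] - a) / tau)
    v0 <- v_inf + (v0 - v_inf) * exp(-(b - a) / tau)
  }
  v
}

# Moments of a normal(mu, sd) truncated to [0, 1]: the exact posterior of
# the linear-Gaussian toy (theta ~ U(0,1), x = theta + N(0, sd^2)).
truncnorm_moments <- function(mu, sd, lo = 0, hi = 1) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  m1 <- mu + sd * (dnorm(a) - dnorm(b)) / z
  var <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                   ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = m1, sd = sqrt(var))
}

# Linear-Gaussian toy simulator: a 2-sample waveform carrying (theta, 0);
# with observation-noise variance sd^2 the posterior given (x0, anything)
# is normal(x0, sd^2) truncated to the unit interval.
toy_simulator <- function() {
  simulator("toy_linear_gaussian", "theta", time_grid(0, 1, 1),
            function(th, seed) c(th[1], 0))
}

toy_prior <- function() {
  prior_spec(data.frame(name = "theta", low = 0, high = 1,
                        transform = "linear"))
}

# Train the toy posterior once per test run (lazy, cached).
toy_posterior <- local({
  cache <- NULL
  function(n = 8000, seed = 71) {
    if (is.null(cache)) {
      ds <- generate_dataset(toy_simulator(), toy_prior(), "identity", n,
                             noise_variance = 0.01, seed = seed)
      cache <<- train_posterior(ds, seed = seed + 1, max_epochs = 100,
                                patience = 10)
    }
    cache
  }
})
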