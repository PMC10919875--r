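#' RC-circuit constants
#'
#' Membrane-analog constants of the resistor-capacitor circuit
#' `C dV/dt = (E - V)/R + I_e(t)`. The constants are treated as
#' dimensionless with time in milliseconds, giving a membrane-like time
#' constant `tau = R * C` of 6 ms under the defaults.
#'
#' @param C Capacitance (> 0). Default 6.
#' @param R Resistance (> 0). Default 1.
#' @param E Rest/source voltage. Default 0.
#' @return An object of class `rc_constants`.
#' @export
rc_constants <- function(C = 6, R = 1, E = 0) {
  stopifnot(is.numeric(C), is.numeric(R), is.numeric(E),
            is.finite(C), is.finite(R), is.finite(E))
  if (C <= 0) stop("capacitance C must be positive")
  if (R <= 0) stop("resistance R must be positive")
  structure(list(C = C, R = R, E = E, tau = R * C), class = "rc_constants")
}

# Validate the 3-parameter vector (i_pos, i_neg, latency) of the RC example.
check_rc_params <- function(i_pos, i_neg, latency) {
  vals <- c(i_pos, i_neg, latency)
  if (!all(is.finite(vals))) stop("RC parameters must be finite")
  if (i_pos < 0) stop("i_pos must be non-negative (magnitude of the positive pulse)")
  if (i_neg < 0) stop("i_neg must be non-negative (magnitude of the negative pulse)")
  invisible(TRUE)
}

#' Injected current of the two-pulse RC drive
#'
#' Builds the injected current `I_e(t)` as the sum of a positive square
#' pulse of magnitude `i_pos` on `[onset, onset + duration)` ms and a
#' negative square pulse of magnitude `i_neg` on
#' `[onset + latency, onset + duration + latency)` ms. Both magnitudes are
#' stored as non-negative numbers; the sign of the second pulse is applied
#' here. With `latency = 0` the pulses overlap exactly and the net current
#' is the single square pulse `i_pos - i_neg`.
#'
#' @param i_pos Magnitude of the positive pulse (mA), `>= 0`.
#' @param i_neg Magnitude of the negative pulse (mA), `>= 0`; applied with
#'   negative sign.
#' @param latency Time shift of the negative pulse (ms); may be negative.
#' @param grid A [time_grid()].
#' @param onset Onset of the positive pulse (ms). Default 80.
#' @param duration Pulse duration (ms). Default 20.
#' @return A [waveform()] with the current (mA) at each grid sample.
#' @examples
#' g <- time_grid()
#' ie <- rc_input_current(0.3, 0.5, 37.5, g)
#' ie[grid_times(g) == 90]   # 0.3
#' ie[grid_times(g) == 120]  # -0.5
#' @export
rc_input_current <- function(i_pos, i_neg, latency, grid = time_grid(),
                             onset = 80, duration = 20) {
  stopifnot(inherits(grid, "time_grid"))
  check_rc_params(i_pos, i_neg, latency)
  windows <- rbind(c(onset, onset + duration),
                   c(onset + latency, onset + duration + latency))
  if (any(windows[, 1] < grid$t_start) || any(windows[, 2] > grid$t_stop)) {
    stop(sprintf(
      paste0("pulse windows [%g, %g) and [%g, %g) ms must lie inside the ",
             "grid span [%g, %g] ms"),
      windows[1, 1], windows[1, 2], windows[2, 1], windows[2, 2],
      grid$t_start, grid$t_stop))
  }
  t <- grid_times(grid)
  ie <- i_pos * (t >= windows[1, 1] & t < windows[1, 2]) -
    i_neg * (t >= windows[2, 1] & t < windows[2, 2])
  waveform(ie, grid)
}

# Unit-amplitude square-pulse voltage response of the RC circuit (E = 0),
# evaluated at times s *relative to pulse onset*: charging toward R while
# the pulse is on, exponential decay after offset. Vectorized over s.
rc_pulse_response <- function(s, duration, R, tau) {
  out <- numeric(length(s))
  on <- s >= 0 & s < duration
  off <- s >= duration
  out[on] <- R * (1 - exp(-s[on] / tau))
  out[off] <- R * (1 - exp(-duration / tau)) * exp(-(s[off] - duration) / tau)
  out
}

#' Simulate the RC-circuit voltage response
#'
#' Integrates `C dV/dt = (E - V)/R + I_e(t)` with `V(t_start) = E` for the
#' two-pulse drive of [rc_input_current()]. Two integration paths are
#' provided: `"analytic"` (default) evaluates the exact piecewise-exponential
#' solution by superposing the closed-form response of each square pulse
#' (the system is linear and time-invariant), and `"ode"` integrates the ODE
#' numerically with an adaptive solver, splitting at the pulse edges so the
#' discontinuous drive never crosses an integration interval.
#'
#' @inheritParams rc_input_current
#' @param consts [rc_constants()].
#' @param method `"analytic"` (exact fast path) or `"ode"` (adaptive
#'   numerical integration, rtol 1e-8).
#' @return A [waveform()] with the voltage at each grid sample.
#' @examples
#' g <- time_grid()
#' v <- simulate_rc(0.1, 0.3, 0, g)   # net -0.2 mA pulse at 80 ms
#' min(v)                             # about -0.193 at t = 100 ms
#' @export
simulate_rc <- function(i_pos, i_neg, latency, grid = time_grid(),
                        consts = rc_constants(),
                        method = c("analytic", "ode"),
                        onset = 80, duration = 20) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "time_grid"), inherits(consts, "rc_constants"))
  check_rc_params(i_pos, i_neg, latency)
  # reuse the window validation
  rc_input_current(i_pos, i_neg, latency, grid, onset, duration)
  t <- grid_times(grid)
  if (method == "analytic") {
    v <- consts$E +
      i_pos * rc_pulse_response(t - onset, duration, consts$R, consts$tau) -
      i_neg * rc_pulse_response(t - (onset + latency), duration,
                                consts$R, consts$tau)
    return(waveform(v, grid))
  }
  # ODE path: piecewise integration between drive breakpoints.
  edges <- sort(unique(c(grid$t_start, grid$t_stop,
                         onset, onset + duration,
                         onset + latency, onset + duration + latency)))
  edges <- edges[edges >= grid$t_start & edges <= grid$t_stop]
  v <- numeric(grid$n)
  v0 <- consts$E
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    mid <- (a + b) / 2
    ie <- i_pos * (mid >= onset & mid < onset + duration) -
      i_neg * (mid >= onset + latency & mid < onset + duration + latency)
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    times <- sort(unique(c(a, t[idx], b)))
    sol <- deSolve::ode(
      y = c(V = v0), times = times,
      func = function(tt, y, p) {
        list((p$E - y[1]) / p$R / p$C + p$ie / p$C)
      },
      parms = list(E = consts$E, R = consts$R, C = consts$C, ie = ie),
      method = "lsoda", rtol = 1e-8, atol = 1e-10
    )
    v[idx] <- sol[match(round(t[idx], 9), round(sol[, 1], 9)), 2]
    v0 <- sol[nrow(sol), 2]
  }
  waveform(v, grid)
}
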