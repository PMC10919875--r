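#' Define a simulator satisfying the plugin contract
#'
#' A simulator is a pure mapping from a parameter vector (plus an optional
#' seed, for stochastic models) to a waveform on a fixed time grid: the same
#' parameter vector and seed must always yield the identical waveform. Any
#' forward model satisfying this contract — including external biophysical
#' simulators such as neural-column dipole models — can be plugged into the
#' dataset-generation, training and diagnostic machinery.
#'
#' @param name Identifier of the simulator.
#' @param param_names Character vector of parameter names, in the order the
#'   simulator expects them (and in which a matching prior lists them).
#' @param grid The [time_grid()] of the output waveforms.
#' @param fn Function `(theta, seed)` mapping a parameter vector to a
#'   numeric vector of length `grid$n`.
#' @param batch_fn Optional vectorized fast path `(theta_matrix, seed)`
#'   returning an `n x T` matrix; must agree with `fn` row by row.
#' @return An object of class `sbi_simulator`.
#' @seealso [rc_simulator()], [simulate_batch()], [simulator_registry()]
#' @export
simulator <- function(name, param_names, grid, fn, batch_fn = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(param_names), length(param_names) >= 1,
            inherits(grid, "time_grid"), is.function(fn))
  structure(
    list(name = name, param_names = param_names, grid = grid,
         fn = fn, batch_fn = batch_fn, d = length(param_names)),
    class = "sbi_simulator"
  )
}

#' @export
print.sbi_simulator <- function(x, ...) {
  cat(sprintf("<sbi_simulator> '%s': %d parameters (%s), %d output samples\n",
              x$name, x$d, paste(x$param_names, collapse = ", "), x$grid$n))
  invisible(x)
}

#' Run one simulation through the contract
#'
#' @param sim An [simulator()].
#' @param theta Parameter vector of length `sim$d`.
#' @param seed Optional integer seed for stochastic simulators.
#' @return A [waveform()].
#' @export
simulate_one <- function(sim, theta, seed = NULL) {
  stopifnot(inherits(sim, "sbi_simulator"))
  theta <- as.numeric(theta)
  if (length(theta) != sim$d) {
    stop(sprintf("expected %d parameters (%s), got %d",
                 sim$d, paste(sim$param_names, collapse = ", "),
                 length(theta)))
  }
  waveform(sim$fn(theta, seed), sim$grid)
}

#' Simulate a batch of parameter vectors
#'
#' Applies a simulator to every row of a parameter matrix. Given the same
#' `theta` and `seed`, the result is bit-for-bit reproducible; row `i`
#' equals `simulate_one(sim, theta[i, ], ...)` exactly (an available
#' vectorized fast path must agree with the scalar map).
#'
#' @param sim An [simulator()].
#' @param theta `n x d` matrix of physical parameter vectors (rows).
#' @param seed Integer seed; for stochastic simulators each row receives a
#'   sub-seed derived from it.
#' @return `n x T` matrix of waveform values (possibly `0 x T`).
#' @export
simulate_batch <- function(sim, theta, seed = 1L) {
  stopifnot(inherits(sim, "sbi_simulator"))
  theta <- as.matrix(theta)
  if (nrow(theta) > 0 && ncol(theta) != sim$d) {
    stop(sprintf("theta has %d columns but simulator '%s' expects %d (%s)",
                 ncol(theta), sim$name, sim$d,
                 paste(sim$param_names, collapse = ", ")))
  }
  n <- nrow(theta)
  if (n == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = sim$grid$n))
  }
  if (!is.null(sim$batch_fn)) {
    out <- sim$batch_fn(theta, seed)
  } else {
    out <- matrix(NA_real_, n, sim$grid$n)
    for (i in seq_len(n)) {
      out[i, ] <- sim$fn(theta[i, ], seed + i - 1L)
    }
  }
  dimnames(out) <- NULL
  out
}

#' The built-in RC-circuit simulator
#'
#' Wraps [simulate_rc()] in the simulator contract with parameters
#' `i_pos`, `i_neg`, `latency` (matching the RC prior preset) and a
#' vectorized analytic batch path used for large training sets.
#'
#' @param grid [time_grid()] of the simulation.
#' @param consts [rc_constants()].
#' @param onset,duration Pulse placement (ms), as in [rc_input_current()].
#' @return An [simulator()] named `"rc_circuit"`.
#' @export
rc_simulator <- function(grid = time_grid(), consts = rc_constants(),
                         onset = 80, duration = 20) {
  t <- grid_times(grid)
  p1 <- rc_pulse_response(t - onset, duration, consts$R, consts$tau)
  batch_fn <- function(theta, seed) {
    n <- nrow(theta)
    lat <- theta[, 3]
    if (any(onset + lat < grid$t_start) ||
        any(onset + duration + lat > grid$t_stop)) {
      stop("negative-pulse window outside the grid span for some rows")
    }
    out <- matrix(NA_real_, n, grid$n)
    chunk <- 4000L
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      idx <- s:e
      # per-row time offsets of the negative pulse
      S <- outer(-(onset + lat[idx]), t, "+")
      P2 <- matrix(rc_pulse_response(S, duration, consts$R, consts$tau),
                   nrow = length(idx))
      out[idx, ] <- consts$E + theta[idx, 1] %o% p1 - theta[idx, 2] * P2
    }
    out
  }
  simulator(
    name = "rc_circuit",
    param_names = c("i_pos", "i_neg", "latency"),
    grid = grid,
    fn = function(theta, seed) {
      as.numeric(simulate_rc(theta[1], theta[2], theta[3], grid, consts,
                             method = "analytic",
                             onset = onset, duration = duration))
    },
    batch_fn = batch_fn
  )
}

# package-local simulator registry
.sim_registry <- new.env(parent = emptyenv())

#' Register or look up simulators by name
#'
#' `register_simulator()` stores a constructor under a name;
#' `get_simulator()` builds a simulator from the registry;
#' `simulator_registry()` lists registered names. The RC circuit is
#' registered at load time; external plugins register their own
#' constructors.
#'
#' @param name Registry key.
#' @param constructor Function `(...)` returning an [simulator()].
#' @param ... Passed to the registered constructor.
#' @return `get_simulator()` returns an `sbi_simulator`;
#'   `simulator_registry()` a character vector of names.
#' @export
register_simulator <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1, is.function(constructor))
  assign(name, constructor, envir = .sim_registry)
  invisible(name)
}

#' @rdname register_simulator
#' @export
get_simulator <- function(name, ...) {
  if (!exists(name, envir = .sim_registry, inherits = FALSE)) {
    stop(sprintf("no simulator '%s' registered; available: %s", name,
                 paste(simulator_registry(), collapse = ", ")))
  }
  get(name, envir = .sim_registry)(...)
}

#' @rdname register_simulator
#' @export
simulator_registry <- function() {
  sort(ls(envir = .sim_registry))
}

.onLoad <- function(libname, pkgname) {
  register_simulator("rc_circuit", rc_simulator)
}
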