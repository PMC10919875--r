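#' Uniform time grid for waveform simulation
#'
#' Defines the sampling grid shared by a simulator and every waveform it
#' produces. Times are in milliseconds and the grid is closed at both ends,
#' so the number of samples is `round((t_stop - t_start) / dt) + 1`.
#'
#' @param t_start Start time (ms).
#' @param t_stop Stop time (ms); must exceed `t_start`.
#' @param dt Sampling step (ms); must be positive and divide the span evenly.
#' @return An object of class `time_grid` with fields `t_start`, `t_stop`,
#'   `dt` and `n` (the sample count).
#' @examples
#' g <- time_grid(0, 250, 0.5)
#' g$n
#' head(grid_times(g))
#' @export
time_grid <- function(t_start = 0, t_stop = 250, dt = 0.5) {
  stopifnot(is.numeric(t_start), is.numeric(t_stop), is.numeric(dt),
            length(t_start) == 1, length(t_stop) == 1, length(dt) == 1,
            is.finite(t_start), is.finite(t_stop), is.finite(dt))
  if (dt <= 0) stop("dt must be positive")
  if (t_stop <= t_start) stop("t_stop must exceed t_start")
  n_steps <- (t_stop - t_start) / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("dt must divide (t_stop - t_start) evenly")
  }
  structure(
    list(t_start = t_start, t_stop = t_stop, dt = dt,
         n = as.integer(round(n_steps)) + 1L),
    class = "time_grid"
  )
}

#' Sample times of a time grid
#'
#' @param grid A [time_grid()].
#' @return Numeric vector of length `grid$n` with the sample times (ms).
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t_start + grid$dt * (seq_len(grid$n) - 1)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> [%g, %g] ms, dt = %g ms, %d samples\n",
              x$t_start, x$t_stop, x$dt, x$n))
  invisible(x)
}

#' Construct a waveform bound to a time grid
#'
#' @param values Numeric vector, one value per grid sample; all finite.
#' @param grid The [time_grid()] the values were sampled on.
#' @return An object of class `waveform` (a numeric vector with the grid
#'   attached as attribute `grid`).
#' @export
waveform <- function(values, grid) {
  stopifnot(inherits(grid, "time_grid"), is.numeric(values))
  if (length(values) != grid$n) {
    stop(sprintf("waveform length %d does not match grid sample count %d",
                 length(values), grid$n))
  }
  if (!all(is.finite(values))) stop("waveform values must all be finite")
  structure(as.numeric(values), grid = grid, class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<waveform> %d samples on [%g, %g] ms; range [%.4g, %.4g]\n",
              g$n, g$t_start, g$t_stop, min(x), max(x)))
  invisible(x)
}

# Coerce a waveform or bare numeric vector to values; checks length.
as_waveform_values <- function(x, grid) {
  v <- unclass(x)
  attributes(v) <- NULL
  if (length(v) != grid$n) {
    stop(sprintf("expected %d samples, got %d", grid$n, length(v)))
  }
  v
}
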