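#' Summary-statistic transforms for waveforms
#'
#' A summary transform maps a waveform of length `T` to a lower-dimensional
#' feature vector used to condition the posterior estimator. Four schemes
#' are provided: `"pca"` (loadings on the leading principal components of a
#' training set, see [fit_pca()]), `"peak"` (magnitude and timing of the
#' maximum and minimum, [peak_features()]), `"bandpower"` (spectral power in
#' four canonical frequency bands, [band_power()]) and `"identity"` (the raw
#' waveform). `apply_summary()` applies a transform to a matrix of
#' waveforms (rows).
#'
#' @param st A summary transform.
#' @param x Waveform matrix (`n x T`), [waveform()], or numeric vector of
#'   length `T`.
#' @return `apply_summary()` returns an `n x m` feature matrix.
#' @name summary_transform
NULL

new_summary_transform <- function(scheme, m, grid, extra = list()) {
  structure(c(list(scheme = scheme, m = m, grid = grid), extra),
            class = c(paste0(scheme, "_summary"), "summary_transform"))
}

#' @export
print.summary_transform <- function(x, ...) {
  cat(sprintf("<summary_transform> scheme '%s', output dimension %d\n",
              x$scheme, x$m))
  if (x$scheme == "pca") {
    cat(sprintf("  cumulative explained variance ratio: %.4f\n",
                sum(x$explained_ratio)))
  }
  invisible(x)
}

#' Identity summary (the raw waveform)
#'
#' @param grid [time_grid()] of the waveforms.
#' @return A summary transform with `m = grid$n`.
#' @export
summary_identity <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  new_summary_transform("identity", grid$n, grid)
}

#' Fit a PCA summary transform
#'
#' Mean-centers the training waveforms and extracts the leading `k`
#' orthonormal principal components via an eigendecomposition of the
#' `T x T` sample covariance (suited to `n >> T` training sets). The
#' per-component explained variance ratios are stored; their total over all
#' `T` components is 1.
#'
#' @param waveforms `n x T` training matrix, `n > k`.
#' @param k Number of components to keep (`1 <= k < min(n, T)`, or `k = T`
#'   when `n > T` for the complete basis).
#' @param grid Optional [time_grid()] recorded with the transform so that
#'   posteriors can verify they are paired with the right sampling.
#' @return A `"pca"` summary transform with fields `center` (length-T mean),
#'   `components` (`k x T`, orthonormal rows), `explained_ratio` (length k)
#'   and `total_variance`.
#' @export
fit_pca <- function(waveforms, k, grid = NULL) {
  x <- as.matrix(waveforms)
  n <- nrow(x); T_ <- ncol(x)
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  if (k > min(n - 1, T_)) {
    stop(sprintf("k = %d too large for %d waveforms of length %d", k, n, T_))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  cov <- crossprod(xc) / (n - 1)
  eig <- eigen(cov, symmetric = TRUE)
  evals <- pmax(eig$values, 0)
  total <- sum(evals)
  if (is.null(grid)) grid <- time_grid(0, T_ - 1, 1)
  new_summary_transform("pca", k, grid, list(
    k = k,
    center = ctr,
    components = t(eig$vectors[, seq_len(k), drop = FALSE]),
    explained_ratio = evals[seq_len(k)] / total,
    all_ratios = evals / total,
    total_variance = total
  ))
}

#' PCA loadings of waveforms
#'
#' @param x Waveform matrix (`n x T`) or a single waveform.
#' @param st A fitted `"pca"` summary transform.
#' @return `n x k` loading matrix `(x - center) %*% t(components)`.
#' @export
pca_transform <- function(x, st) {
  stopifnot(inherits(st, "pca_summary"))
  x <- to_wave_matrix(x, length(st$center))
  sweep(x, 2, st$center) %*% t(st$components)
}

#' Reconstruct waveforms from PCA loadings
#'
#' Computes `center + loadings %*% components`. On data lying in the span
#' of the kept components, `pca_inverse(pca_transform(x))` recovers `x`;
#' in general the squared reconstruction error equals the variance in the
#' discarded components.
#'
#' @param loadings `n x k` matrix of loadings.
#' @param st A fitted `"pca"` summary transform.
#' @return `n x T` matrix of reconstructed waveforms.
#' @export
pca_inverse <- function(loadings, st) {
  stopifnot(inherits(st, "pca_summary"))
  loadings <- to_wave_matrix(loadings, st$k)
  sweep(loadings %*% st$components, 2, st$center, "+")
}

#' Peak summary transform and features
#'
#' `peak_features()` returns the 4-vector (maximum value, time of maximum,
#' minimum value, time of minimum) of a waveform; ties are broken by the
#' earliest sample. `summary_peak()` wraps it as a transform.
#'
#' @param x A [waveform()], or a numeric vector with `times` supplied.
#' @param times Sample times, required when `x` is a bare vector.
#' @return Named numeric 4-vector `(max, t_max, min, t_min)`.
#' @export
peak_features <- function(x, times = NULL) {
  if (inherits(x, "waveform") && is.null(times)) {
    times <- grid_times(attr(x, "grid"))
  }
  v <- as.numeric(x)
  if (length(v) == 0) stop("waveform must be non-empty")
  stopifnot(length(times) == length(v))
  i_max <- which.max(v)
  i_min <- which.min(v)
  c(max = v[i_max], t_max = times[i_max], min = v[i_min], t_min = times[i_min])
}

#' @rdname peak_features
#' @param grid [time_grid()] of the waveforms.
#' @export
summary_peak <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  new_summary_transform("peak", 4L, grid)
}

#' Band-power summary transform and features
#'
#' `band_power()` computes the power of a waveform in four half-open
#' frequency bands — 0-13 Hz (alpha and below), 13-30 Hz (beta), 30-50 Hz
#' (low gamma) and 50-80 Hz (high gamma) — from a one-sided
#' rectangular-window periodogram. The grid must resolve 80 Hz
#' (`dt <= 6.25` ms). `summary_bandpower()` wraps it as a transform.
#'
#' @param x A [waveform()], or numeric vector with `dt` supplied.
#' @param dt Sampling step in ms, required when `x` is a bare vector.
#' @param bands 2-column matrix of band edges in Hz (half-open `[lo, hi)`).
#' @return Named numeric 4-vector of non-negative band powers.
#' @export
band_power <- function(x, dt = NULL,
                       bands = rbind(c(0, 13), c(13, 30), c(30, 50), c(50, 80))) {
  if (inherits(x, "waveform") && is.null(dt)) {
    dt <- attr(x, "grid")$dt
  }
  v <- as.numeric(x)
  n <- length(v)
  stopifnot(is.numeric(dt), length(dt) == 1, n >= 2)
  fs <- 1000 / dt  # Hz; dt is in ms
  if (fs / 2 < max(bands)) {
    stop(sprintf("grid too coarse: dt = %g ms resolves only %g Hz, need %g Hz",
                 dt, fs / 2, max(bands)))
  }
  spec <- abs(stats::fft(v))^2 / n^2
  half <- floor(n / 2)
  freqs <- (0:half) * fs / n
  psd <- spec[1:(half + 1)]
  # fold the negative frequencies onto the positive side
  dbl <- 2:(half + if (n %% 2 == 0) 0 else 1)
  psd[dbl] <- 2 * psd[dbl]
  out <- apply(bands, 1, function(b) sum(psd[freqs >= b[1] & freqs < b[2]]))
  names(out) <- apply(bands, 1, function(b) sprintf("%g-%gHz", b[1], b[2]))
  out
}

#' @rdname band_power
#' @param grid [time_grid()] of the waveforms.
#' @export
summary_bandpower <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (1000 / grid$dt / 2 < 80) {
    stop("grid too coarse for the 50-80 Hz band; need dt <= 6.25 ms")
  }
  new_summary_transform("bandpower", 4L, grid)
}

#' @rdname summary_transform
#' @export
apply_summary <- function(st, x) {
  stopifnot(inherits(st, "summary_transform"))
  switch(st$scheme,
    identity = to_wave_matrix(x, st$grid$n),
    pca = pca_transform(x, st),
    peak = {
      x <- to_wave_matrix(x, st$grid$n)
      times <- grid_times(st$grid)
      t(apply(x, 1, peak_features, times = times))
    },
    bandpower = {
      x <- to_wave_matrix(x, st$grid$n)
      t(apply(x, 1, band_power, dt = st$grid$dt))
    }
  )
}

#' Add Gaussian observation noise to waveforms
#'
#' Adds independent zero-mean Gaussian noise of the given variance to every
#' sample, reproducibly for a fixed seed. Variance 0 returns the input
#' unchanged.
#'
#' @param x Waveform matrix (`n x T`) or vector.
#' @param variance Noise variance (`>= 0`).
#' @param seed Integer seed.
#' @return Object of the same shape with noise added.
#' @export
add_observation_noise <- function(x, variance, seed = 1L) {
  stopifnot(is.numeric(variance), length(variance) == 1, is.finite(variance))
  if (variance < 0) stop("noise variance must be non-negative")
  if (variance == 0) return(x)
  noise <- with_seed(seed, stats::rnorm(length(x), sd = sqrt(variance)))
  if (is.matrix(x)) {
    x + matrix(noise, nrow(x), ncol(x))
  } else {
    x + noise
  }
}

# Coerce input to an n x T numeric matrix of waveforms (rows).
to_wave_matrix <- function(x, T_) {
  if (is.null(dim(x))) {
    v <- as.numeric(x)
    if (length(v) != T_) {
      stop(sprintf("expected waveforms of length %d, got %d", T_, length(v)))
    }
    matrix(v, 1, T_)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != T_) {
      stop(sprintf("expected waveforms of length %d, got %d", T_, ncol(x)))
    }
    storage.mode(x) <- "double"
    x
  }
}
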