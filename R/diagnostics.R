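#' Parameter recovery error (PRE)
#'
#' The 2-Wasserstein distance between the empirical marginal posterior of
#' parameter `k` and a point mass at the ground truth — equivalently the
#' root mean squared deviation of the unit-space samples from
#' `theta0_unit[k]`:
#' `PRE_k = sqrt(mean((theta_i[k] - theta0[k])^2))`.
#' With parameters normalized to `(0, 1)` the value is bounded in
#' `[0, 1]`: 0 means perfect recovery (a degenerate posterior at the
#' truth), 1 the worst possible (a degenerate posterior at the opposite
#' end of the range). The squared variant (no square root) is available
#' via `squared = TRUE`.
#'
#' @param samples_unit `N x d` matrix of posterior samples in unit-cube
#'   coordinates.
#' @param theta0_unit Ground-truth parameter vector in unit coordinates.
#' @param k Parameter index (or vector of indices); default all.
#' @param squared Return the mean squared deviation instead of its root.
#' @return Numeric vector of PRE values, one per requested index.
#' @examples
#' parameter_recovery_error(matrix(c(0.2, 0.4), 2, 1), 0.3)  # 0.1
#' @export
parameter_recovery_error <- function(samples_unit, theta0_unit, k = NULL,
                                     squared = FALSE) {
  s <- as.matrix(samples_unit)
  if (nrow(s) == 0) stop("need at least one posterior sample")
  theta0_unit <- as.numeric(theta0_unit)
  stopifnot(length(theta0_unit) == ncol(s))
  if (min(s) < -1e-9 || max(s) > 1 + 1e-9 ||
      min(theta0_unit) < -1e-9 || max(theta0_unit) > 1 + 1e-9) {
    stop("PRE expects unit-space inputs in [0, 1]; map with physical_to_unit()")
  }
  if (is.null(k)) k <- seq_len(ncol(s))
  out <- vapply(k, function(j) mean((s[, j] - theta0_unit[j])^2), numeric(1))
  if (!squared) out <- sqrt(out)
  names(out) <- colnames(s)[k]
  out
}

#' Posterior predictive check (PPC)
#'
#' Average discrepancy between re-simulations from posterior samples and
#' the conditioning observation: the mean over draws of the Euclidean norm
#' of the residual, `PPC = mean_i ||x_i - x0||_2`. Zero iff every
#' predictive draw equals `x0` exactly. `per_sample = TRUE` divides each
#' norm by `sqrt(T)` for a per-sample RMSE scale.
#'
#' @param x_pred `N x T` matrix of posterior-predictive waveforms.
#' @param x0 Conditioning waveform (length `T`).
#' @param per_sample Normalize each norm by `sqrt(T)`.
#' @return Non-negative scalar.
#' @export
posterior_predictive_check <- function(x_pred, x0, per_sample = FALSE) {
  x_pred <- as.matrix(x_pred)
  x0 <- as.numeric(x0)
  if (ncol(x_pred) != length(x0)) {
    stop(sprintf("predictive draws have %d samples but x0 has %d",
                 ncol(x_pred), length(x0)))
  }
  norms <- sqrt(rowSums(sweep(x_pred, 2, x0)^2))
  if (per_sample) norms <- norms / sqrt(length(x0))
  mean(norms)
}

#' Overlap coefficient (OVL) of two marginal densities
#'
#' The integral of the pointwise minimum of two normalized densities over
#' the prior support: 1 means identical distributions, 0 disjoint ones.
#' `overlap_coefficient()` conditions a trained posterior on two
#' observations, evaluates both joint densities on an evenly spaced
#' tensor grid with `grid_points` points per dimension over the unit
#' cube, marginalizes to parameter `k` by summation, normalizes each
#' marginal to unit mass, and returns the sum of the pointwise minimum.
#' `overlap_from_densities()` is the same numerical core for arbitrary
#' (e.g. mock) joint density functions. For dimensions above `max_d` the
#' tensor grid is refused; use the sample-based [overlap_from_samples()]
#' fallback instead.
#'
#' @param post A [train_posterior()] result.
#' @param x0,x1 The two conditioning observations.
#' @param k Parameter index (or vector of indices) of the marginal(s) to
#'   compare.
#' @param grid_points Grid resolution per dimension (default 50).
#' @param max_d Largest dimension for which the tensor grid is attempted.
#' @return Numeric vector in `[0, 1]`, one value per requested index.
#' @export
overlap_coefficient <- function(post, x0, x1, k, grid_points = 50,
                                max_d = 4) {
  stopifnot(inherits(post, "posterior_approximation"))
  d <- post$prior$d
  f0 <- function(u) exp(posterior_log_density(post, u, x0, space = "unit"))
  f1 <- function(u) exp(posterior_log_density(post, u, x1, space = "unit"))
  overlap_from_densities(f0, f1, d, k, grid_points = grid_points,
                         max_d = max_d)
}

#' @rdname overlap_coefficient
#' @param f0,f1 Functions mapping an `n x d` matrix of unit-cube points to
#'   `n` (possibly unnormalized) non-negative density values.
#' @param d Number of parameters.
#' @export
overlap_from_densities <- function(f0, f1, d, k, grid_points = 50,
                                   max_d = 4) {
  stopifnot(all(k >= 1), all(k <= d))
  if (d > max_d) {
    stop(sprintf(
      "tensor grid with %d^%d points refused (d > %d); use overlap_from_samples()",
      grid_points, d, max_d))
  }
  pts <- (seq_len(grid_points) - 0.5) / grid_points  # cell midpoints
  grid <- as.matrix(expand.grid(rep(list(pts), d)))
  dimnames(grid) <- NULL
  p0 <- f0(grid); p1 <- f1(grid)
  if (any(p0 < 0) || any(p1 < 0)) stop("densities must be non-negative")
  if (sum(p0) <= 0 || sum(p1) <= 0) stop("density mass is zero on the grid")
  vapply(k, function(kk) {
    kcol <- grid[, kk]
    m0 <- vapply(pts, function(v) sum(p0[kcol == v]), numeric(1))
    m1 <- vapply(pts, function(v) sum(p1[kcol == v]), numeric(1))
    m0 <- m0 / sum(m0)
    m1 <- m1 / sum(m1)
    sum(pmin(m0, m1))
  }, numeric(1))
}

#' Sample-based overlap coefficient fallback
#'
#' Estimates the marginal OVL from posterior samples via Gaussian kernel
#' density estimates on a common grid over `[0, 1]` — the documented
#' fallback when the joint tensor grid is infeasible (`d > 4`).
#'
#' @param samples0_unit,samples1_unit Unit-space sample matrices.
#' @param k Parameter index.
#' @param grid_points Evaluation grid resolution.
#' @return Scalar in `[0, 1]`.
#' @export
overlap_from_samples <- function(samples0_unit, samples1_unit, k,
                                 grid_points = 50) {
  s0 <- as.matrix(samples0_unit)[, k]
  s1 <- as.matrix(samples1_unit)[, k]
  pts <- (seq_len(grid_points) - 0.5) / grid_points
  d0 <- stats::density(s0, from = 0, to = 1, n = 512)
  d1 <- stats::density(s1, from = 0, to = 1, n = 512)
  m0 <- stats::approx(d0$x, d0$y, xout = pts, rule = 2)$y
  m1 <- stats::approx(d1$x, d1$y, xout = pts, rule = 2)$y
  m0 <- m0 / sum(m0)
  m1 <- m1 / sum(m1)
  sum(pmin(m0, m1))
}

#' Local diagnostic grid of PRE and PPC values
#'
#' Lays an evenly spaced grid over the prior support — `resolution` points
#' per dimension spanning `range` (default `[0.05, 0.95]`) in unit
#' coordinates — and at each grid point: simulates the ground-truth
#' waveform, draws posterior samples conditioned on it, computes the
#' per-parameter PRE, and re-simulates from `n_ppc_sims` posterior draws
#' for the PPC. The result table underlies the local diagnostic heatmaps;
#' [grid_slice()] reduces it to 2-D panels.
#'
#' @param post A trained [train_posterior()] result.
#' @param sim The simulator the posterior was trained on.
#' @param resolution Grid points per dimension (default 10).
#' @param range Unit-space range spanned in each dimension.
#' @param n_post_samples Posterior samples per grid point (default 1000).
#' @param n_ppc_sims Re-simulations per grid point for the PPC.
#' @param seed Integer seed.
#' @return An object of class `diagnostic_grid`: a data.frame with the
#'   unit coordinates (`u_<name>`), per-parameter `pre_<name>` columns and
#'   a `ppc` column, plus metadata attributes.
#' @export
diagnostic_grid <- function(post, sim, resolution = 10,
                            range = c(0.05, 0.95), n_post_samples = 1000,
                            n_ppc_sims = 50, seed = 1L) {
  stopifnot(inherits(post, "posterior_approximation"),
            inherits(sim, "sbi_simulator"))
  prior <- post$prior
  d <- prior$d
  pts <- seq(range[1], range[2], length.out = resolution)
  grid_u <- as.matrix(expand.grid(rep(list(pts), d)))
  dimnames(grid_u) <- NULL
  n_pts <- nrow(grid_u)
  pre <- matrix(NA_real_, n_pts, d)
  ppc <- rep(NA_real_, n_pts)
  ok <- rep(TRUE, n_pts)
  for (i in seq_len(n_pts)) {
    res <- tryCatch({
      theta0 <- unit_to_physical(grid_u[i, ], prior)
      x0 <- simulate_batch(sim, theta0, seed = seed + 7L * i)[1, ]
      samp <- posterior_sample(post, n_post_samples, x0,
                               seed = seed + 7L * i + 1L)
      su <- attr(samp, "unit")
      pre_i <- parameter_recovery_error(su, grid_u[i, ])
      idx <- seq_len(min(n_ppc_sims, nrow(samp)))
      x_pred <- simulate_batch(sim, samp[idx, , drop = FALSE],
                               seed = seed + 7L * i + 2L)
      list(pre = pre_i, ppc = posterior_predictive_check(x_pred, x0))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE
    } else {
      pre[i, ] <- res$pre
      ppc[i] <- res$ppc
    }
  }
  out <- data.frame(grid_u, pre, ppc)
  names(out) <- c(paste0("u_", prior$name), paste0("pre_", prior$name), "ppc")
  out$ok <- ok
  structure(out, class = c("diagnostic_grid", "data.frame"),
            resolution = resolution, range = range,
            n_post_samples = n_post_samples, n_ppc_sims = n_ppc_sims,
            seed = seed, param_names = prior$name)
}

#' 2-D heatmap slice of a diagnostic grid
#'
#' Reduces a [diagnostic_grid()] table to a 2-D matrix over two displayed
#' dimensions by averaging (default) or taking the maximum of a value
#' column over all remaining dimensions.
#'
#' @param grid A [diagnostic_grid()].
#' @param value Column to display (e.g. `"pre_i_pos"` or `"ppc"`).
#' @param dims Character or integer pair: the two displayed parameters.
#' @param reduce `"mean"` or `"max"` over the non-displayed dimensions.
#' @return Matrix with the displayed dimensions as rows/columns
#'   (dimnames carry the unit coordinates).
#' @export
grid_slice <- function(grid, value, dims, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(grid, "diagnostic_grid"))
  pn <- attr(grid, "param_names")
  if (is.numeric(dims)) dims <- pn[dims]
  stopifnot(length(dims) == 2, all(dims %in% pn), value %in% names(grid))
  ux <- grid[[paste0("u_", dims[1])]]
  uy <- grid[[paste0("u_", dims[2])]]
  v <- grid[[value]]
  fn <- if (reduce == "mean") {
    function(z) mean(z, na.rm = TRUE)
  } else {
    function(z) max(z, na.rm = TRUE)
  }
  tab <- tapply(v, list(ux, uy), fn)
  tab
}

#' Pearson correlation between posterior-sample columns
#'
#' @param samples Posterior sample matrix.
#' @param j,k Column indices (or names).
#' @return List with `estimate` (Pearson r), `p_value` (two-sided) and
#'   `defined` (`FALSE` when a column has zero variance, in which case the
#'   estimate is `NA`).
#' @export
posterior_correlation <- function(samples, j, k) {
  s <- as.matrix(samples)
  if (nrow(s) < 3) stop("need at least 3 samples")
  x <- s[, j]; y <- s[, k]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p_value = NA_real_, defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, defined = TRUE)
}

#' Pair-plot data export
#'
#' Builds the data behind a pair-plot of a multivariate posterior: one
#' kernel density curve per parameter (the diagonal) and one scatter panel
#' per parameter pair (below the diagonal). The export is
#' backend-agnostic; any plotting layer can render it.
#'
#' @param samples `N x d` matrix of posterior samples (unit or physical).
#' @param names Parameter names; defaults to column names.
#' @return An object of class `pairplot_data`: list with `densities`
#'   (per-parameter data.frames with `x`, `density`), `scatter`
#'   (per-pair data.frames with the two coordinates), `names` and `n`.
#' @export
pairplot_export <- function(samples, names = NULL) {
  s <- as.matrix(samples)
  d <- ncol(s)
  if (d < 1) stop("need at least one parameter")
  if (is.null(names)) names <- colnames(s)
  if (is.null(names)) names <- paste0("theta", seq_len(d))
  dens <- lapply(seq_len(d), function(j) {
    kd <- stats::density(s[, j])
    data.frame(x = kd$x, density = kd$y)
  })
  names(dens) <- names
  pairs <- list()
  if (d >= 2) {
    for (j in seq_len(d - 1)) {
      for (k in (j + 1):d) {
        df <- data.frame(s[, j], s[, k])
        colnames(df) <- names[c(j, k)]
        pairs[[paste(names[j], names[k], sep = ":")]] <- df
      }
    }
  }
  structure(list(densities = dens, scatter = pairs, names = names,
                 n = nrow(s)),
            class = "pairplot_data")
}

#' @export
print.pairplot_data <- function(x, ...) {
  cat(sprintf("<pairplot_data> %d samples, %d parameters, %d scatter panels\n",
              x$n, length(x$names), length(x$scatter)))
  invisible(x)
}
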