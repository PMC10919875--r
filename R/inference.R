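#' Generate a simulation training dataset
#'
#' Samples `n` parameter vectors from the prior (uniform on the unit cube,
#' mapped to physical units), simulates the corresponding waveforms, adds
#' Gaussian observation noise, and extracts summary statistics. When
#' `summary` is a fit request of the form `list(scheme = "pca", k = 30)`
#' the PCA transform is fitted on this (noisy) dataset and returned with
#' it; a ready-made transform is applied as is.
#'
#' @param sim An [simulator()]; parameter order must match the prior.
#' @param prior A [prior_spec()].
#' @param summary A fitted summary transform, a fit request
#'   `list(scheme = "pca", k = <count>)`, or one of the scheme names
#'   `"identity"`, `"peak"`, `"bandpower"`.
#' @param n Number of simulations.
#' @param noise_variance Variance of the Gaussian observation noise added
#'   to the raw waveforms before summary extraction (0.01 for the shipped
#'   RC example).
#' @param seed Integer seed driving prior sampling, simulation and noise.
#' @param keep_waveforms Keep the (noisy) waveform matrix in the result
#'   (needed to refit summaries; off by default to save memory).
#' @return An object of class `simulation_dataset` with fields
#'   `theta_unit`, `theta_physical`, `summaries`, `summary` (the fitted
#'   transform), optional `waveforms`, and `meta` (seed, simulator id,
#'   noise variance, prior).
#' @export
generate_dataset <- function(sim, prior, summary, n, noise_variance = 0,
                             seed = 1L, keep_waveforms = FALSE) {
  stopifnot(inherits(sim, "sbi_simulator"), inherits(prior, "prior_spec"))
  if (prior$d != sim$d) {
    stop(sprintf("prior has %d parameters but simulator '%s' expects %d",
                 prior$d, sim$name, sim$d))
  }
  n <- as.integer(n)
  u <- sample_unit(prior, n, seed = seed)
  theta <- unit_to_physical(u, prior)
  x <- tryCatch(simulate_batch(sim, theta, seed = seed + 1L),
                error = function(e) NULL)
  if (is.null(x)) {
    # batch failed: simulate row by row, resampling failed rows a bounded
    # number of times before giving up
    x <- matrix(NA_real_, n, sim$grid$n)
    for (i in seq_len(n)) {
      for (try in 0:5) {
        res <- tryCatch(sim$fn(theta[i, ], seed + 1L + i),
                        error = function(e) e)
        if (!inherits(res, "error")) break
        if (try == 5) {
          stop(sprintf("simulator '%s' failed repeatedly near row %d: %s",
                       sim$name, i, conditionMessage(res)))
        }
        message(sprintf("resampling failed simulation row %d", i))
        u[i, ] <- with_seed(seed + 31L * i + try,
                            stats::runif(prior$d))
        theta[i, ] <- unit_to_physical(u[i, , drop = FALSE], prior)
      }
      x[i, ] <- res
    }
  }
  x <- add_observation_noise(x, noise_variance, seed = seed + 2L)
  st <- resolve_summary(summary, sim$grid, x)
  s <- apply_summary(st, x)
  if (!all(is.finite(s))) stop("non-finite summary statistics in dataset")
  structure(
    list(theta_unit = u, theta_physical = theta, summaries = s,
         summary = st,
         waveforms = if (keep_waveforms) x else NULL,
         meta = list(n = n, seed = seed, simulator = sim$name,
                     noise_variance = noise_variance, prior = prior,
                     grid = sim$grid)),
    class = "simulation_dataset"
  )
}

#' @export
print.simulation_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulation_dataset> %d simulations of '%s'; %d parameters, %d summary features (%s)\n",
    x$meta$n, x$meta$simulator, ncol(x$theta_unit), ncol(x$summaries),
    x$summary$scheme))
  invisible(x)
}

resolve_summary <- function(summary, grid, waveforms = NULL) {
  if (inherits(summary, "summary_transform")) return(summary)
  if (is.character(summary) && length(summary) == 1) {
    return(switch(summary,
      identity = summary_identity(grid),
      peak = summary_peak(grid),
      bandpower = summary_bandpower(grid),
      stop(sprintf("unknown summary scheme '%s'", summary))))
  }
  if (is.list(summary) && identical(summary$scheme, "pca")) {
    if (is.null(waveforms)) stop("a PCA fit request needs training waveforms")
    return(fit_pca(waveforms, summary$k, grid = grid))
  }
  stop("summary must be a summary_transform, a scheme name, or list(scheme = 'pca', k = ...)")
}

#' Train an amortized posterior approximation
#'
#' Fits a conditional masked autoregressive flow to the (unit-space
#' parameter, summary) pairs of a simulation dataset, by maximum
#' likelihood with minibatch Adam and early stopping on a validation
#' split. The result is amortized: the one trained estimator can be
#' conditioned on any observation in summary space without retraining.
#' Training operates in unit parameter space; [posterior_sample()] maps
#' draws back to physical units.
#'
#' @param data A [generate_dataset()] result.
#' @param n_transforms Number of stacked autoregressive transforms.
#' @param hidden_units Hidden units per transform conditioner.
#' @param learning_rate,batch_size,max_epochs,patience,val_frac Optimizer
#'   settings; early stopping monitors validation loss with the given
#'   patience.
#' @param min_n Minimum training-set size accepted.
#' @param seed Integer seed for initialization, split and shuffling.
#' @param verbose Print per-epoch validation loss.
#' @return An object of class `posterior_approximation` bound to the
#'   dataset's prior, simulator grid and summary transform; carries the
#'   validation-loss trajectory in `training`.
#' @export
train_posterior <- function(data, n_transforms = 5, hidden_units = 50,
                            learning_rate = 1e-3, batch_size = 256,
                            max_epochs = 200, patience = 20, val_frac = 0.1,
                            min_n = 1000, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(data, "simulation_dataset"))
  if (nrow(data$theta_unit) < min_n) {
    stop(sprintf("training needs at least %d simulations, got %d",
                 min_n, nrow(data$theta_unit)))
  }
  flow <- maf_fit(data$theta_unit, data$summaries,
                  n_transforms = n_transforms, hidden = hidden_units,
                  lr = learning_rate, batch_size = batch_size,
                  max_epochs = max_epochs, patience = patience,
                  val_frac = val_frac, seed = seed, verbose = verbose)
  structure(
    list(flow = flow, prior = data$meta$prior, summary = data$summary,
         grid = data$meta$grid, simulator = data$meta$simulator,
         training = list(n_train = data$meta$n, seed = seed,
                         val_loss = flow$val_loss,
                         val_trace = flow$val_trace,
                         epochs = flow$epochs_run,
                         n_transforms = n_transforms,
                         hidden_units = hidden_units)),
    class = "posterior_approximation"
  )
}

#' @export
print.posterior_approximation <- function(x, ...) {
  cat(sprintf(
    "<posterior_approximation> %d-parameter flow conditioned on %d '%s' features\n",
    x$prior$d, x$summary$m, x$summary$scheme))
  cat(sprintf("  trained on %d simulations of '%s'; val NLL %.4f after %d epochs\n",
              x$training$n_train, x$simulator, x$training$val_loss,
              x$training$epochs))
  invisible(x)
}

# Turn an observation (waveform of length T, or a summary vector of
# length m) into the conditioning feature vector.
condition_features <- function(post, x0) {
  v <- as.numeric(x0)
  T_ <- post$grid$n
  m <- post$summary$m
  if (length(v) == T_ && !(m == T_ && post$summary$scheme != "identity")) {
    return(as.numeric(apply_summary(post$summary, v)))
  }
  if (length(v) == m) return(v)
  stop(sprintf(
    "observation must be a waveform of length %d or a summary vector of length %d",
    T_, m))
}

#' Draw posterior samples for an observation
#'
#' Conditions the trained flow on `x0` and draws `n` samples; proposals
#' falling outside the prior support (the unit cube) are rejected and
#' redrawn, with a warning if the acceptance rate drops below
#' `min_acceptance`. Samples are returned in physical units; the
#' unit-space counterparts are attached as attribute `"unit"`.
#'
#' @param post A [train_posterior()] result.
#' @param n Number of samples.
#' @param x0 Conditioning observation: waveform (length `T`) or summary
#'   vector (length `m`).
#' @param seed Integer seed.
#' @param min_acceptance Warn when the rejection-sampling acceptance rate
#'   falls below this value.
#' @return `n x d` matrix of physical parameter samples with attribute
#'   `"unit"` (same shape, unit cube).
#' @export
posterior_sample <- function(post, n, x0, seed = 1L, min_acceptance = 0.05) {
  stopifnot(inherits(post, "posterior_approximation"), n >= 1)
  ctx <- condition_features(post, x0)
  d <- post$prior$d
  accepted <- matrix(numeric(0), 0, d)
  proposed <- 0
  draw <- n
  attempt <- 0
  while (nrow(accepted) < n) {
    attempt <- attempt + 1
    if (attempt > 1000) stop("posterior sampling failed: acceptance rate ~ 0")
    cand <- maf_sample(post$flow, draw, ctx, seed = seed + attempt - 1L)
    proposed <- proposed + draw
    ok <- rowSums(cand < 0 | cand > 1) == 0
    accepted <- rbind(accepted, cand[ok, , drop = FALSE])
    rate <- max(nrow(accepted), 1) / proposed
    draw <- min(max(ceiling((n - nrow(accepted)) / max(rate, 0.01)), n), 1e5)
  }
  rate <- nrow(accepted) / proposed
  if (rate < min_acceptance) {
    warning(sprintf(
      "low prior-support acceptance rate in posterior sampling: %.3f", rate))
  }
  u <- accepted[seq_len(n), , drop = FALSE]
  colnames(u) <- post$prior$name
  theta <- unit_to_physical(u, post$prior)
  attr(theta, "unit") <- u
  theta
}

#' Posterior log density at parameter values
#'
#' Evaluates the trained flow density (conditioned on `x0`) at the given
#' parameter values. Values outside the prior support have zero density
#' (`-Inf` log density). By default `theta` is interpreted in physical
#' units and the density is reported in unit-cube coordinates, the space
#' the estimator is trained and the overlap diagnostics operate in.
#'
#' @param post A [train_posterior()] result.
#' @param theta `n x d` matrix (or d-vector) of parameter values.
#' @param x0 Conditioning observation (waveform or summary vector).
#' @param space `"physical"` (default) or `"unit"`: the coordinates
#'   `theta` is given in.
#' @return Numeric vector of log densities (unit-cube scale).
#' @export
posterior_log_density <- function(post, theta, x0,
                                  space = c("physical", "unit")) {
  stopifnot(inherits(post, "posterior_approximation"))
  space <- match.arg(space)
  ctx <- condition_features(post, x0)
  theta <- to_param_matrix(theta, post$prior$d)
  u <- if (space == "physical") {
    lo <- post$prior$low; hi <- post$prior$high
    out_of_range <- vapply(seq_len(post$prior$d), function(j) {
      theta[, j] < lo[j] | theta[, j] > hi[j]
    }, logical(nrow(theta)))
    out_of_range <- matrix(out_of_range, nrow = nrow(theta))
    u <- theta
    inside <- rowSums(out_of_range) == 0
    u[inside, ] <- physical_to_unit(theta[inside, , drop = FALSE], post$prior)
    attr(u, "inside") <- inside
    u
  } else theta
  inside <- attr(u, "inside")
  if (is.null(inside)) inside <- rowSums(u < 0 | u > 1) == 0
  ld <- rep(-Inf, nrow(u))
  if (any(inside)) {
    ld[inside] <- maf_log_density(post$flow, u[inside, , drop = FALSE], ctx)
  }
  ld
}
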