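#' @name maf
#' @title Masked autoregressive flow for conditional density estimation
#'
#' @description
#' A conditional masked autoregressive flow (MAF): a stack of Gaussian MADE
#' transforms, each an autoregressive conditioner `z_i -> (mu_i, alpha_i)`
#' computed by a single-hidden-layer network with masked weights so that
#' the i-th output depends only on `z_{<i}` plus the conditioning features.
#' Each transform maps `u = (z - mu) * exp(-alpha)`; dimensions are
#' reversed between transforms; the base density is standard normal. The
#' flow is trained by maximum likelihood with Adam on minibatches,
#' hand-derived backpropagation, and early stopping on a validation split.
#' Targets and conditioning features are standardized internally (the
#' affine Jacobian is accounted for in the reported densities).
#'
#' These are the estimator internals; the user-facing interface is
#' [train_posterior()] / [posterior_sample()] / [posterior_log_density()].
#' @keywords internal
NULL

# ---- MADE layer -----------------------------------------------------------

made_init <- function(d, m, hidden, rng_sd = 0.05) {
  # degrees: inputs 1..d; hidden cycle over 1..max(d-1, 1); for d = 1 the
  # conditioner sees only the context.
  indeg <- seq_len(d)
  if (d > 1) {
    hdeg <- rep(seq_len(d - 1), length.out = hidden)
    m1 <- outer(hdeg, indeg, ">=") * 1          # hidden x d
    m2 <- outer(seq_len(d), hdeg, ">") * 1      # d x hidden
  } else {
    m1 <- matrix(0, hidden, 1)
    m2 <- matrix(0, 1, hidden)
  }
  gl <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(1 / max(fan_in, 1))), nr, nc)
  }
  list(
    m1 = m1, m2 = m2,
    W1 = gl(hidden, d, d) * m1,            # hidden <- z
    U1 = gl(hidden, m, m),                 # hidden <- context
    b1 = numeric(hidden),
    W2mu = gl(d, hidden, hidden) * m2,     # mu <- hidden
    Vmu = gl(d, m, m) * 0.01,              # mu <- context (direct)
    bmu = numeric(d),
    W2a = matrix(0, d, hidden),            # alpha <- hidden (identity start)
    Va = matrix(0, d, m),
    ba = numeric(d)
  )
}

# forward pass of one MADE conditioner; returns mu, alpha and caches
made_forward <- function(lay, z, ctx, cap = 7) {
  pre <- z %*% t(lay$W1) + ctx %*% t(lay$U1) +
    matrix(lay$b1, nrow(z), length(lay$b1), byrow = TRUE)
  a <- tanh(pre)
  mu <- a %*% t(lay$W2mu) + ctx %*% t(lay$Vmu) +
    matrix(lay$bmu, nrow(z), ncol(z), byrow = TRUE)
  ar <- a %*% t(lay$W2a) + ctx %*% t(lay$Va) +
    matrix(lay$ba, nrow(z), ncol(z), byrow = TRUE)
  alpha <- cap * tanh(ar / cap)
  list(mu = mu, alpha = alpha, a = a)
}

# backward pass: g_mu, g_alpha are dL/dmu, dL/dalpha (batch x d).
# Returns parameter gradients and dL/dz (through the conditioner only).
made_backward <- function(lay, z, ctx, cache, g_mu, g_alpha, cap = 7) {
  g_ar <- g_alpha * (1 - (cache$alpha / cap)^2)
  g_a <- g_mu %*% (lay$W2mu) + g_ar %*% (lay$W2a)
  g_pre <- g_a * (1 - cache$a^2)
  list(
    grads = list(
      W1 = (t(g_pre) %*% z) * lay$m1,
      U1 = t(g_pre) %*% ctx,
      b1 = colSums(g_pre),
      W2mu = (t(g_mu) %*% cache$a) * lay$m2,
      Vmu = t(g_mu) %*% ctx,
      bmu = colSums(g_mu),
      W2a = (t(g_ar) %*% cache$a) * lay$m2,
      Va = t(g_ar) %*% ctx,
      ba = colSums(g_ar)
    ),
    g_z = g_pre %*% lay$W1
  )
}

# ---- flow forward / backward ---------------------------------------------

# density-direction pass through the whole stack.
# Returns per-sample negative log-likelihood and caches for backprop.
maf_forward <- function(layers, y, ctx, cap = 7) {
  n <- nrow(y); d <- ncol(y)
  z <- y
  caches <- vector("list", length(layers))
  zs <- vector("list", length(layers))
  sum_alpha <- matrix(0, n, 1)
  for (k in seq_along(layers)) {
    zs[[k]] <- z
    cc <- made_forward(layers[[k]], z, ctx, cap)
    caches[[k]] <- cc
    u <- (z - cc$mu) * exp(-cc$alpha)
    sum_alpha <- sum_alpha + rowSums(cc$alpha)
    z <- u[, d:1, drop = FALSE]  # reverse dimension order between transforms
  }
  nll <- 0.5 * rowSums(z^2) + as.numeric(sum_alpha) + 0.5 * d * log(2 * pi)
  list(nll = nll, z_final = z, caches = caches, zs = zs)
}

# gradients of mean NLL over the batch w.r.t. all layer parameters
maf_backward <- function(layers, y, ctx, fw, cap = 7) {
  n <- nrow(y); d <- ncol(y)
  g_z <- fw$z_final / n  # d(mean NLL)/dz_final
  grads <- vector("list", length(layers))
  for (k in rev(seq_along(layers))) {
    g_u <- g_z[, d:1, drop = FALSE]  # undo the reversal
    cc <- fw$caches[[k]]
    z_in <- fw$zs[[k]]
    u <- (z_in - cc$mu) * exp(-cc$alpha)
    e <- exp(-cc$alpha)
    g_mu <- -g_u * e
    g_alpha <- -g_u * u + 1 / n  # 1/n from the mean of sum(alpha)
    bk <- made_backward(layers[[k]], z_in, ctx, cc, g_mu, g_alpha, cap)
    grads[[k]] <- bk$grads
    g_z <- g_u * e + bk$g_z
  }
  grads
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(l) {
    pn <- setdiff(names(l), c("m1", "m2"))
    list(m = lapply(l[pn], function(p) p * 0),
         v = lapply(l[pn], function(p) p * 0))
  })
}

adam_step <- function(layers, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (k in seq_along(layers)) {
    for (pn in names(state[[k]]$m)) {
      g <- grads[[k]][[pn]]
      state[[k]]$m[[pn]] <- b1 * state[[k]]$m[[pn]] + (1 - b1) * g
      state[[k]]$v[[pn]] <- b2 * state[[k]]$v[[pn]] + (1 - b2) * g^2
      mhat <- state[[k]]$m[[pn]] / (1 - b1^t)
      vhat <- state[[k]]$v[[pn]] / (1 - b2^t)
      layers[[k]][[pn]] <- layers[[k]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# ---- fit / evaluate / sample ---------------------------------------------

std_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

std_apply <- function(x, s) sweep(sweep(x, 2, s$center), 2, s$scale, "/")

# Fit a conditional MAF by maximum likelihood.
maf_fit <- function(y, ctx, n_transforms = 5, hidden = 50, lr = 1e-3,
                    batch_size = 256, max_epochs = 200, patience = 20,
                    val_frac = 0.1, seed = 1L, cap = 7, verbose = FALSE) {
  y <- as.matrix(y); ctx <- as.matrix(ctx)
  stopifnot(nrow(y) == nrow(ctx), nrow(y) >= 10)
  d <- ncol(y); m <- ncol(ctx)
  y_std <- std_fit(y); ctx_std <- std_fit(ctx)
  ys <- std_apply(y, y_std); cs <- std_apply(ctx, ctx_std)
  n <- nrow(ys)

  with_seed(seed, {
    layers <- lapply(seq_len(n_transforms), function(k) made_init(d, m, hidden))
    perm <- sample.int(n)
    n_val <- max(1L, floor(val_frac * n))
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
    y_tr <- ys[tr_idx, , drop = FALSE]; c_tr <- cs[tr_idx, , drop = FALSE]
    y_val <- ys[val_idx, , drop = FALSE]; c_val <- cs[val_idx, , drop = FALSE]
    n_tr <- nrow(y_tr)

    state <- adam_state(layers)
    step <- 0
    best_val <- Inf
    best_layers <- layers
    wait <- 0
    val_trace <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      for (s0 in seq(1L, n_tr, by = batch_size)) {
        bi <- ord[s0:min(s0 + batch_size - 1L, n_tr)]
        yb <- y_tr[bi, , drop = FALSE]; cb <- c_tr[bi, , drop = FALSE]
        fw <- maf_forward(layers, yb, cb, cap)
        if (!all(is.finite(fw$nll))) {
          stop("non-finite training loss in flow fitting; inspect inputs")
        }
        grads <- maf_backward(layers, yb, cb, fw, cap)
        step <- step + 1
        upd <- adam_step(layers, grads, state, lr, step)
        layers <- upd$layers; state <- upd$state
      }
      val_loss <- mean(maf_forward(layers, y_val, c_val, cap)$nll)
      val_trace <- c(val_trace, val_loss)
      if (verbose) message(sprintf("epoch %d: val NLL %.4f", epoch, val_loss))
      if (val_loss < best_val - 1e-5) {
        best_val <- val_loss
        best_layers <- layers
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  })
  structure(
    list(layers = best_layers, d = d, m = m, cap = cap,
         y_std = y_std, ctx_std = ctx_std,
         n_transforms = n_transforms, hidden = hidden,
         val_loss = best_val, val_trace = val_trace,
         epochs_run = length(val_trace), seed = seed),
    class = "maf"
  )
}

#' @export
print.maf <- function(x, ...) {
  cat(sprintf(
    "<maf> d = %d, context dim = %d, %d transforms x %d hidden; val NLL %.4f (%d epochs)\n",
    x$d, x$m, x$n_transforms, x$hidden, x$val_loss, x$epochs_run))
  invisible(x)
}

# log density of rows of y (original scale) given context rows
maf_log_density <- function(flow, y, ctx) {
  y <- to_param_matrix(y, flow$d)
  ctx <- to_param_matrix(ctx, flow$m)
  if (nrow(ctx) == 1 && nrow(y) > 1) {
    ctx <- ctx[rep(1, nrow(y)), , drop = FALSE]
  }
  ys <- std_apply(y, flow$y_std)
  cs <- std_apply(ctx, flow$ctx_std)
  fw <- maf_forward(flow$layers, ys, cs, flow$cap)
  -fw$nll - sum(log(flow$y_std$scale))
}

# draw n samples given one context row (original scale)
maf_sample <- function(flow, n, ctx1, seed = 1L) {
  ctx1 <- to_param_matrix(ctx1, flow$m)
  cs <- std_apply(ctx1, flow$ctx_std)[rep(1, n), , drop = FALSE]
  d <- flow$d
  z <- with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  for (k in rev(seq_along(flow$layers))) {
    u <- z[, d:1, drop = FALSE]  # undo the inter-transform reversal
    zk <- matrix(0, n, d)
    for (i in seq_len(d)) {
      cc <- made_forward(flow$layers[[k]], zk, cs, flow$cap)
      zk[, i] <- u[, i] * exp(cc$alpha[, i]) + cc$mu[, i]
    }
    z <- zk
  }
  sweep(sweep(z, 2, flow$y_std$scale, "*"), 2, flow$y_std$center, "+")
}
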