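#' Gaussian mean-field posterior over synaptic weights
#'
#' Each weight has an independent Gaussian `N(m, 1/p)` with mean `m` and
#' precision `p > 0`. `m` and `p` may be numeric vectors/matrices or lists of
#' matrices (one per network layer).
#'
#' @param m Means.
#' @param p Precisions (strictly positive; floored at `p_floor`).
#' @param p_floor Lower bound applied to precisions.
#' @return A `gaussian_posterior`.
#' @export
gaussian_posterior <- function(m, p, p_floor = 1e-6) {
  p <- smap(function(x) pmax(x, p_floor), p)
  chk <- function(x) all(is.finite(unlist(x)))
  if (!chk(m) || !chk(p)) stop("posterior parameters must be finite", call. = FALSE)
  structure(list(m = m, p = p, p_floor = p_floor), class = "gaussian_posterior")
}

#' Gaussian prior over synaptic weights
#'
#' @param m0 Prior means (scalar or shaped like the posterior).
#' @param p0 Prior precisions (> 0).
#' @return A `gaussian_prior`.
#' @export
gaussian_prior <- function(m0 = 0, p0 = 1) {
  if (any(unlist(p0) <= 0)) stop("prior precisions must be positive", call. = FALSE)
  structure(list(m0 = m0, p0 = p0), class = "gaussian_prior")
}

#' Variational-inference training configuration
#'
#' @param rho Free-energy temperature (>= 0): weight of the KL term tying the
#'   posterior to the prior. `eta * rho < 1` is required so the precision
#'   update stays a valid convex combination.
#' @param eta Learning rate.
#' @param n_mc Posterior samples per update (each sample is shared across the
#'   mini-batch replicas).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param p_floor Precision floor guarding against numerical collapse.
#' @param seed Integer seed.
#' @return A `vi_config`.
#' @export
vi_config <- function(rho = 0.1, eta = 0.05, n_mc = 1L, batch_size = 16L,
                      epochs = 10L, p_floor = 1e-6, seed = 1L) {
  if (rho < 0) stop("`rho` must be nonnegative", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  if (eta * rho >= 1) {
    stop("`eta * rho` must be below 1 (precision update would leave the convex regime)",
         call. = FALSE)
  }
  if (n_mc < 1L) stop("`n_mc` must be at least 1", call. = FALSE)
  structure(list(rho = rho, eta = eta, n_mc = as.integer(n_mc),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 p_floor = p_floor, seed = as.integer(seed)),
            class = "vi_config")
}

# map f elementwise over a numeric object or a list of numeric objects;
# additional arguments may be scalars or objects of matching structure.
smap <- function(f, x, ...) {
  extras <- list(...)
  if (is.list(x)) {
    lapply(seq_along(x), function(i) {
      args <- lapply(extras, function(e) if (is.list(e)) e[[i]] else e)
      do.call(f, c(list(x[[i]]), args))
    })
  } else {
    do.call(f, c(list(x), extras))
  }
}

# sum of f applied elementwise over a (possibly list) structure
ssum <- function(f, x, ...) {
  v <- smap(f, x, ...)
  if (is.list(v)) sum(vapply(v, sum, 0)) else sum(v)
}

#' Draw weights from a Gaussian posterior
#'
#' `w = m + xi / sqrt(p)` with `xi` i.i.d. standard normal.
#'
#' @param post A [gaussian_posterior()].
#' @param seed Optional seed (NULL draws from the current RNG stream).
#' @return Weights shaped like `post$m`.
#' @export
sample_weights <- function(post, seed = NULL) {
  draw <- function(m, p) m + matrix(stats::rnorm(length(m)), nrow = NROW(m)) /
    sqrt(p)
  draw_v <- function(m, p) if (is.matrix(m)) draw(m, p) else
    m + stats::rnorm(length(m)) / sqrt(p)
  with_seed(seed, smap(draw_v, post$m, post$p))
}

#' Natural-gradient precision update
#'
#' `p <- (1 - eta*rho) * p + eta * (sq_grad_batch_mean + rho * p0)`, floored at
#' the configured precision floor. `sq_grad_batch_mean` is the batch mean of
#' the per-example squared gradient, evaluated at weights sampled from the
#' current posterior (the square is taken per example, before averaging).
#'
#' @param post A [gaussian_posterior()].
#' @param sq_grad_batch_mean Batch-mean squared gradients, shaped like
#'   `post$p`.
#' @param prior A [gaussian_prior()].
#' @param cfg A [vi_config()].
#' @return The updated posterior.
#' @export
update_precision <- function(post, sq_grad_batch_mean, prior, cfg) {
  floor_p <- max(post$p_floor, cfg$p_floor)
  post$p <- smap(function(p, sq, p0) {
    pmax((1 - cfg$eta * cfg$rho) * p + cfg$eta * (sq + cfg$rho * p0), floor_p)
  }, post$p, sq_grad_batch_mean, prior$p0)
  post
}

#' Natural-gradient mean update
#'
#' `m <- m - eta * (1/p_new) * (grad_batch_mean - rho * p0 * (m0 - m))`, where
#' `p_new` is the precision already advanced by [update_precision()].
#'
#' @param post Posterior whose precision has already been advanced.
#' @param grad_batch_mean Batch-mean gradients, shaped like `post$m`.
#' @param prior A [gaussian_prior()].
#' @param cfg A [vi_config()].
#' @return The updated posterior.
#' @export
update_mean <- function(post, grad_batch_mean, prior, cfg) {
  post$m <- smap(function(m, g, p, m0, p0) {
    m - cfg$eta / p * (g - cfg$rho * p0 * (m0 - m))
  }, post$m, grad_batch_mean, post$p, prior$m0, prior$p0)
  post
}

#' KL divergence between diagonal Gaussian posterior and prior
#'
#' Sum over weights of
#' `0.5 * (p0/p + p0*(m - m0)^2 - 1 + log(p/p0))`.
#'
#' @param post A [gaussian_posterior()].
#' @param prior A [gaussian_prior()].
#' @return Scalar KL divergence.
#' @export
gaussian_kl <- function(post, prior) {
  ssum(function(m, p, m0, p0) {
    0.5 * (p0 / p + p0 * (m - m0)^2 - 1 + log(p / p0))
  }, post$m, post$p, prior$m0, prior$p0)
}

# broadcast scalar prior entries to the structure of the posterior parameters
conform_prior <- function(prior, template) {
  bc <- function(x) {
    if (is.list(template) && !is.list(x)) {
      lapply(template, function(tm) array(x, dim = dim(tm) %||% length(tm)))
    } else x
  }
  gaussian_prior(m0 = bc(prior$m0), p0 = bc(prior$p0))
}

#' Gaussian variational optimization of a generic loss
#'
#' Runs the natural-gradient updates on an arbitrary differentiable loss: at
#' every iteration `n_mc` weight vectors are drawn from the current posterior,
#' `grad_fn` supplies the loss gradient at each sample, and the precision/mean
#' updates are applied (precision first). Useful for low-dimensional problems
#' where the free energy can be tracked in closed form.
#'
#' @param grad_fn Function `w -> gradient` (same shape as `w`).
#' @param prior A [gaussian_prior()].
#' @param cfg A [vi_config()].
#' @param n_iter Number of iterations.
#' @param init Optional initial posterior (defaults to the prior).
#' @param keep_trace Record the parameter trajectory.
#' @return List with `posterior` and (if `keep_trace`) tibble `trace` holding
#'   the per-iteration means and precisions (1-D problems) or their norms.
#' @export
gaussian_vi_optimize <- function(grad_fn, prior, cfg, n_iter = 1000L,
                                 init = NULL, keep_trace = TRUE) {
  post <- init %||% gaussian_posterior(prior$m0, prior$p0, p_floor = cfg$p_floor)
  d <- length(post$m)
  m_tr <- if (keep_trace) matrix(NA_real_, n_iter, d)
  p_tr <- if (keep_trace) matrix(NA_real_, n_iter, d)
  with_seed(cfg$seed, {
    for (it in seq_len(n_iter)) {
      g <- 0; sq <- 0
      for (s in seq_len(cfg$n_mc)) {
        w <- sample_weights(post)
        gs <- grad_fn(w)
        g <- g + gs
        sq <- sq + gs^2
      }
      post <- update_precision(post, sq / cfg$n_mc, prior, cfg)
      post <- update_mean(post, g / cfg$n_mc, prior, cfg)
      if (keep_trace) { m_tr[it, ] <- post$m; p_tr[it, ] <- post$p }
    }
  })
  out <- list(posterior = post)
  if (keep_trace) {
    out$trace <- tibble::tibble(iter = seq_len(n_iter),
                                m = if (d == 1L) m_tr[, 1] else rowMeans(m_tr),
                                p = if (d == 1L) p_tr[, 1] else rowMeans(p_tr))
    if (d > 1L) { out$m_trace <- m_tr; out$p_trace <- p_tr }
  }
  out
}

# mean dataset loss (sum over layers and time of the local losses, averaged
# over examples) for fixed weights
dataset_loss <- function(net, weights, dataset, chunk = 64L) {
  n <- dim(dataset$x)[3]
  total <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- srm_forward(net, dataset$x[, , idx, drop = FALSE], weights)
    yb <- one_hot_matrix(dataset$labels[idx], net$n_classes)
    for (l in seq_len(net$n_layers)) {
      for (t in seq_len(dataset$T)) {
        S <- matrix(fwd$spikes[[l]][, t, ], nrow = net$layer_sizes[l + 1L])
        total <- total + sum(local_loss_batch(S, yb, net$readout[[l]]))
      }
    }
  }
  total / n
}

#' Bayesian offline training with a Gaussian posterior
#'
#' Mean-field Gaussian variational inference for a layered SRM. At every
#' time-step of every mini-batch: a weight sample is drawn from the current
#' posterior (shared across the batch replicas; `n_mc` independent replica
#' sets are simulated when `n_mc > 1`), surrogate gradients of the per-layer
#' local losses are computed at the sampled weights, and the natural-gradient
#' precision and mean updates are applied in that order. After each epoch a
#' Monte-Carlo estimate of the variational free energy (expected dataset loss
#' plus `rho` times the closed-form Gaussian KL to the prior) is recorded.
#'
#' @param net A [layered_srm()].
#' @param dataset A `spike_dataset`.
#' @param prior A [gaussian_prior()] (scalar entries are broadcast).
#' @param cfg A [vi_config()].
#' @param init Optional initial posterior.
#' @param fe_samples Posterior draws used for the per-epoch free-energy
#'   estimate.
#' @return An `svi_fit` with `posterior`, `prior`, `fe_trace` (tibble
#'   epoch/free_energy), the net and config.
#' @export
train_gaussian_vi <- function(net, dataset, prior = gaussian_prior(),
                              cfg = vi_config(), init = NULL, fe_samples = 2L) {
  stopifnot(inherits(dataset, "spike_dataset"))
  n <- dim(dataset$x)[3]
  if (n == 0L) stop("empty dataset", call. = FALSE)
  shapes <- lapply(init_weights(net, seed = 1L), function(w) w * 0)
  prior <- conform_prior(prior, shapes)
  if (is.null(init)) {
    # posterior means start at a standard random initialization (a zero-mean
    # start would leave the network silent); precisions start at the prior's
    init <- gaussian_posterior(init_weights(net, seed = cfg$seed),
                               prior$p0, p_floor = cfg$p_floor)
  }
  post <- init
  fe <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(n, cfg$batch_size, cfg$seed + 131L * epoch)
      for (batch in batches) {
        xb <- dataset$x[, , batch, drop = FALSE]
        yb <- one_hot_matrix(dataset$labels[batch], net$n_classes)
        post <- gaussian_vi_batch_pass(net, post, prior, xb, yb, cfg)
      }
      el <- mean(vapply(seq_len(fe_samples), function(s) {
        dataset_loss(net, sample_weights(post), dataset)
      }, 0))
      fe[epoch] <- el + cfg$rho * gaussian_kl(post, prior)
    }
  })
  structure(list(posterior = post, prior = prior, net = net, cfg = cfg,
                 family = "gaussian",
                 fe_trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                           free_energy = fe)),
            class = "svi_fit")
}

# one online mini-batch pass for Gaussian VI; n_mc independent replica sets
# share the batch but draw their own weights each step.
gaussian_vi_batch_pass <- function(net, post, prior, xb, yb, cfg) {
  T_steps <- dim(xb)[2]
  n_b <- dim(xb)[3]
  L <- net$n_layers
  mk_states <- function() lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  mk_prev <- function() lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  states_mc <- replicate(cfg$n_mc, mk_states(), simplify = FALSE)
  prev_mc <- replicate(cfg$n_mc, mk_prev(), simplify = FALSE)
  for (t in seq_len(T_steps)) {
    g_acc <- lapply(seq_len(L), function(l) 0)
    sq_acc <- lapply(seq_len(L), function(l) 0)
    for (s in seq_len(cfg$n_mc)) {
      w <- sample_weights(post)
      pre_now <- matrix(xb[, t, ], nrow = net$layer_sizes[1])
      for (l in seq_len(L)) {
        states_mc[[s]][[l]] <- step_filters(states_mc[[s]][[l]], pre_now,
                                            prev_mc[[s]][[l]], net$filters)
        u <- membrane_potential(w[[l]], states_mc[[s]][[l]]$syn_traces,
                                if (net$refractory) states_mc[[s]][[l]]$ref_traces else NULL)
        sp <- fire(u, net$thresholds[l])
        e <- error_signal_batch(sp, yb, net$readout[[l]])
        ep <- e * post_sensitivity(u, net$thresholds[l])
        gr <- layer_grad_step(ep, states_mc[[s]][[l]]$syn_traces, sq = TRUE)
        g_acc[[l]] <- g_acc[[l]] + gr$g / cfg$n_mc
        sq_acc[[l]] <- sq_acc[[l]] + gr$sq / cfg$n_mc
        prev_mc[[s]][[l]] <- sp
        pre_now <- sp
      }
    }
    post <- update_precision(post, sq_acc, prior, cfg)
    post <- update_mean(post, g_acc, prior, cfg)
  }
  post
}

#' @export
print.svi_fit <- function(x, ...) {
  cat(sprintf("<svi_fit: %s posterior, %d epochs, final free energy %.4f>\n",
              x$family, nrow(x$fe_trace), utils::tail(x$fe_trace$free_energy, 1)))
  invisible(x)
}
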