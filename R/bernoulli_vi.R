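#' Bernoulli mean-field posterior over binary synapses
#'
#' Each binary weight `w in {+1, -1}` has an independent posterior
#' parameterized by a logit `w^r`: `P(w = +1) = sigma(2 w^r)` and mean
#' `mu = tanh(w^r)`. Logits may be numeric vectors/matrices or per-layer lists
#' of matrices.
#'
#' @param logits Per-synapse logits.
#' @return A `bernoulli_posterior` with accessors `$prob` and `$mu`.
#' @export
bernoulli_posterior <- function(logits) {
  if (!all(is.finite(unlist(logits)))) stop("logits must be finite", call. = FALSE)
  structure(list(logits = logits,
                 prob = smap(function(l) sigmoid(2 * l), logits),
                 mu = smap(tanh, logits)),
            class = "bernoulli_posterior")
}

#' Bernoulli prior over binary synapses
#'
#' @param logits0 Prior logits; 0 makes +1 and -1 equally likely.
#' @return A `bernoulli_prior`.
#' @export
bernoulli_prior <- function(logits0 = 0) {
  if (!all(is.finite(unlist(logits0)))) stop("prior logits must be finite", call. = FALSE)
  structure(list(logits0 = logits0), class = "bernoulli_prior")
}

#' Gumbel-softmax training configuration
#'
#' @param tau Gumbel-softmax temperature (> 0). The gradient estimator is
#'   unbiased only in the limit `tau -> 0`; moderate values trade bias for
#'   variance and stability.
#' @param eta Learning rate.
#' @param rho Free-energy temperature (`eta * rho < 1`).
#' @param n_mc Gumbel draws averaged per update.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param logit_clip Symmetric bound applied to the logits after every update.
#'   Saturated logits (probabilities within ~1e-9 of 0 or 1) carry no usable
#'   gradient information but make the relaxed-sample estimator heavy-tailed;
#'   clipping at 10 is behaviorally inert while keeping the updates stable.
#'   Set to `Inf` to disable.
#' @param seed Integer seed.
#' @return A `gs_config`.
#' @export
gs_config <- function(tau = 1, eta = 0.05, rho = 0.1, n_mc = 1L,
                      batch_size = 16L, epochs = 10L, logit_clip = 10,
                      seed = 1L) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  if (rho < 0) stop("`rho` must be nonnegative", call. = FALSE)
  if (eta * rho >= 1) stop("`eta * rho` must be below 1", call. = FALSE)
  if (logit_clip <= 0) stop("`logit_clip` must be positive", call. = FALSE)
  structure(list(tau = tau, eta = eta, rho = rho, n_mc = as.integer(n_mc),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 logit_clip = logit_clip, seed = as.integer(seed)),
            class = "gs_config")
}

#' Probability/logit conversion for binary +-1 weights
#'
#' `w^r = 0.5 * log(p / (1 - p))`, the inverse of `p = sigma(2 w^r)`.
#'
#' @param p Probability of `w = +1`, strictly inside (0, 1).
#' @return Logit(s).
#' @export
prob_to_logit <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  0.5 * log(p / (1 - p))
}

#' Gumbel-softmax relaxed weight sample
#'
#' Draws `delta = 0.5 * log(eps / (1 - eps))` with `eps ~ U(0,1)` per synapse
#' and returns the relaxed weights `w = tanh((logits + delta) / tau)`, which
#' lie strictly in (-1, 1) and concentrate on +-1 as `tau -> 0`.
#'
#' @param logits Posterior logits (numeric or per-layer list).
#' @param cfg A [gs_config()] (only `tau` is used).
#' @param seed Optional seed.
#' @return Relaxed weights shaped like `logits`.
#' @export
gumbel_sample <- function(logits, cfg, seed = NULL) {
  draw <- function(l) {
    eps <- stats::runif(length(l))
    delta <- 0.5 * log(eps / (1 - eps))
    w <- tanh((l + delta) / cfg$tau)
    if (is.matrix(l)) matrix(w, nrow = nrow(l)) else w
  }
  with_seed(seed, smap(draw, logits))
}

#' Hard +-1 sample from a Bernoulli posterior
#'
#' The `tau -> 0` limit of [gumbel_sample()]: `w = sign(logits + delta)` with
#' `sign(0) = +1`. Used at evaluation time, where binary synapses must be
#' exactly +-1.
#'
#' @inheritParams gumbel_sample
#' @return Weights in \{+1, -1\} shaped like `logits`.
#' @export
hard_sample <- function(logits, seed = NULL) {
  draw <- function(l) {
    eps <- stats::runif(length(l))
    delta <- 0.5 * log(eps / (1 - eps))
    w <- ifelse(l + delta >= 0, 1, -1)
    if (is.matrix(l)) matrix(w, nrow = nrow(l)) else w
  }
  with_seed(seed, smap(draw, logits))
}

#' Gumbel-softmax estimate of the mean-parameter gradient
#'
#' Converts a loss gradient taken at the relaxed weights into an (approximately
#' unbiased as `tau -> 0`) estimate of the gradient with respect to the
#' Bernoulli mean parameters:
#' `dL_dw * (1 - w^2) / (tau * (1 - tanh(logits)^2))`.
#'
#' @param dL_dw Loss gradient evaluated at the sampled relaxed weights.
#' @param w The relaxed weights from [gumbel_sample()] (same draw).
#' @param logits The logits the sample was drawn from.
#' @param cfg A [gs_config()].
#' @return Gradient estimate shaped like `logits`.
#' @export
grad_estimate <- function(dL_dw, w, logits, cfg) {
  smap(function(g, ww, l) {
    num <- 1 - ww^2
    den <- cfg$tau * (1 - tanh(l)^2)
    # a fully saturated relaxed sample carries zero gradient (avoid 0/0)
    out <- ifelse(num == 0, 0, g * num / pmax(den, 1e-300))
    if (is.matrix(l)) matrix(out, nrow = nrow(l)) else out
  }, dL_dw, w, logits)
}

#' Natural-gradient logit update
#'
#' `w^r <- (1 - eta*rho) * w^r - eta * (grad_mu_batch_mean - rho * w0^r)`.
#'
#' @param logits Current logits.
#' @param grad_mu_batch_mean Batch-averaged [grad_estimate()].
#' @param prior A [bernoulli_prior()].
#' @param cfg A [gs_config()].
#' @return Updated logits.
#' @export
update_logits <- function(logits, grad_mu_batch_mean, prior, cfg) {
  clip <- cfg$logit_clip %||% Inf
  smap(function(l, g, l0) {
    out <- (1 - cfg$eta * cfg$rho) * l - cfg$eta * (g - cfg$rho * l0)
    pmin(pmax(out, -clip), clip)
  }, logits, grad_mu_batch_mean, prior$logits0)
}

#' KL divergence between Bernoulli posterior and prior
#'
#' Sum over synapses of `p*log(p/p0) + (1-p)*log((1-p)/(1-p0))` with
#' `p = sigma(2 w^r)`, `p0 = sigma(2 w0^r)`.
#'
#' @param post A [bernoulli_posterior()].
#' @param prior A [bernoulli_prior()].
#' @return Scalar KL divergence.
#' @export
bernoulli_kl <- function(post, prior) {
  ssum(function(l, l0) {
    p <- sigmoid(2 * l); p0 <- sigmoid(2 * l0)
    p * (log(p) - log(p0)) + (1 - p) * (log1p(-p) - log1p(-p0))
  }, post$logits, prior$logits0)
}

# broadcast scalar prior logits to the posterior's structure
conform_bernoulli_prior <- function(prior, template) {
  l0 <- prior$logits0
  if (is.list(template) && !is.list(l0)) {
    l0 <- lapply(template, function(tm) array(l0, dim = dim(tm) %||% length(tm)))
  }
  bernoulli_prior(l0)
}

## ---- enumeration oracles for small binary-weight problems ----------------

#' All +-1 weight configurations
#'
#' @param n Number of binary weights (kept small; `2^n` rows are produced).
#' @return A `2^n x n` matrix of +-1 values.
#' @export
enum_configs <- function(n) {
  stopifnot(n >= 1, n <= 20)
  as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
}

# log-probability of each configuration under independent Bernoulli(logits)
enum_log_q <- function(configs, logits) {
  lp <- t(t(configs) * logits)  # w * wr
  rowSums(lp - log(2 * cosh(logits))[col(lp)])
}

#' Exact free energy of a factorized Bernoulli posterior (by enumeration)
#'
#' `F = E_q[L] + rho * KL(q || prior)` with the expectation computed exactly
#' over all `2^n` configurations.
#'
#' @param loss_fn Function taking a +-1 weight vector, returning the loss.
#' @param logits Posterior logits (length n).
#' @param prior_logits Prior logits (scalar or length n).
#' @param rho Temperature.
#' @return Scalar free energy.
#' @export
bernoulli_free_energy_enum <- function(loss_fn, logits, prior_logits, rho) {
  n <- length(logits)
  configs <- enum_configs(n)
  q <- exp(enum_log_q(configs, logits))
  losses <- apply(configs, 1, loss_fn)
  el <- sum(q * losses)
  kl <- bernoulli_kl(bernoulli_posterior(logits),
                     bernoulli_prior(rep(prior_logits, length.out = n)))
  el + rho * kl
}

#' Free energy of the enumerated Gibbs posterior
#'
#' The unconstrained minimizer of the free energy is the Gibbs posterior
#' `q* proportional to prior(w) * exp(-L(w)/rho)`; its free energy equals
#' `-rho * log E_prior[exp(-L/rho)]`, computed here exactly by enumeration.
#' It lower-bounds the free energy of every (in particular every factorized)
#' distribution.
#'
#' @inheritParams bernoulli_free_energy_enum
#' @param n Number of binary weights.
#' @return Scalar free energy of the Gibbs posterior.
#' @export
gibbs_free_energy <- function(loss_fn, n, prior_logits, rho) {
  configs <- enum_configs(n)
  log_prior <- enum_log_q(configs, rep(prior_logits, length.out = n))
  losses <- apply(configs, 1, loss_fn)
  a <- log_prior - losses / rho
  -rho * (max(a) + log(sum(exp(a - max(a)))))
}

#' Best factorized posterior by exhaustive coordinate search
#'
#' Minimizes the enumerated free energy over product Bernoulli distributions
#' by exact coordinate updates: with all other coordinates fixed, the optimal
#' probability for coordinate i is `sigma(logit2(p0) - a_i / rho)` where `a_i`
#' is the exactly enumerated difference of conditional expected losses. Run
#' from several random starts; the best solution is returned.
#'
#' @inheritParams gibbs_free_energy
#' @param n_restarts Random restarts.
#' @param max_sweeps Coordinate sweeps per restart.
#' @param tol Convergence tolerance on the free energy.
#' @param seed Seed for the restarts.
#' @return List with `logits` and `free_energy` of the best solution found.
#' @export
bernoulli_coordinate_search <- function(loss_fn, n, prior_logits, rho,
                                        n_restarts = 5L, max_sweeps = 100L,
                                        tol = 1e-10, seed = 1L) {
  configs <- enum_configs(n)
  losses <- apply(configs, 1, loss_fn)
  l0 <- rep(prior_logits, length.out = n)
  fe_of <- function(logits) {
    q <- exp(enum_log_q(configs, logits))
    sum(q * losses) + rho * bernoulli_kl(bernoulli_posterior(logits),
                                         bernoulli_prior(l0))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      logits <- if (r == 1L) rep(0, n) else stats::rnorm(n)
      fe <- fe_of(logits)
      for (sweep in seq_len(max_sweeps)) {
        for (i in seq_len(n)) {
          others <- exp(enum_log_q(configs[, -i, drop = FALSE],
                                   logits[-i]))
          plus <- configs[, i] > 0
          e_plus <- sum(others[plus] * losses[plus]) / sum(others[plus])
          e_minus <- sum(others[!plus] * losses[!plus]) / sum(others[!plus])
          # optimal p_i = sigma(2*l0_i - (E[L|+1]-E[L|-1])/rho); store as logit
          logits[i] <- 0.5 * (2 * l0[i] - (e_plus - e_minus) / rho)
        }
        fe_new <- fe_of(logits)
        if (abs(fe - fe_new) < tol) { fe <- fe_new; break }
        fe <- fe_new
      }
      if (is.null(best) || fe < best$free_energy) {
        best <- list(logits = logits, free_energy = fe)
      }
    }
  })
  best
}

#' Exact mean-parameter gradient by enumeration
#'
#' `d E_q[L] / d mu_i` for a product Bernoulli posterior with means
#' `mu = tanh(logits)`, computed exactly over all configurations.
#'
#' @inheritParams bernoulli_free_energy_enum
#' @return Numeric vector of length n.
#' @export
bernoulli_mu_grad_enum <- function(loss_fn, logits) {
  n <- length(logits)
  mu <- tanh(logits)
  configs <- enum_configs(n)
  losses <- apply(configs, 1, loss_fn)
  vapply(seq_len(n), function(i) {
    others <- (1 + t(t(configs[, -i, drop = FALSE]) * mu[-i])) / 2
    w_others <- apply(others, 1, prod)
    sum(w_others * configs[, i] / 2 * losses)
  }, 0)
}

#' Bernoulli variational optimization of a generic loss
#'
#' Runs the Gumbel-softmax natural-gradient logit updates on an arbitrary
#' differentiable loss: per iteration, `n_mc` relaxed samples are drawn,
#' `grad_fn` supplies `dL/dw` at each, the [grad_estimate()] multiplier maps
#' them to mean-parameter gradients, and [update_logits()] is applied.
#'
#' @param grad_fn Function `w -> dL/dw` at relaxed weights `w`.
#' @param prior A [bernoulli_prior()].
#' @param cfg A [gs_config()].
#' @param n_iter Iterations.
#' @param init Optional initial logits (defaults to the prior logits).
#' @param n_weights Number of weights (needed when the prior is scalar).
#' @return List with the final `posterior` and tibble `trace` of logit norms.
#' @export
bernoulli_vi_optimize <- function(grad_fn, prior, cfg, n_iter = 1000L,
                                  init = NULL, n_weights = NULL) {
  logits <- init %||% rep(prior$logits0, length.out = n_weights %||% length(prior$logits0))
  prior <- bernoulli_prior(rep(prior$logits0, length.out = length(logits)))
  tr <- numeric(n_iter)
  with_seed(cfg$seed, {
    for (it in seq_len(n_iter)) {
      g <- 0
      for (s in seq_len(cfg$n_mc)) {
        w <- gumbel_sample(logits, cfg)
        g <- g + grad_estimate(grad_fn(w), w, logits, cfg) / cfg$n_mc
      }
      logits <- update_logits(logits, g, prior, cfg)
      tr[it] <- sqrt(mean(logits^2))
    }
  })
  list(posterior = bernoulli_posterior(logits),
       trace = tibble::tibble(iter = seq_len(n_iter), logit_rms = tr))
}

#' Bayesian offline training of binary synapses
#'
#' Bernoulli mean-field variational inference for a layered SRM with binary
#' weights. At every time-step a relaxed weight sample is drawn via the
#' Gumbel-softmax reparameterization (shared across the batch replicas), the
#' network runs forward with those relaxed weights (spiking dynamics stay
#' binary), surrogate gradients `dL/dw` are computed, converted by the
#' chain-rule multiplier to mean-parameter gradient estimates, and the
#' natural-gradient logit update is applied. Evaluation uses hard +-1 samples
#' ([hard_sample()]). After each epoch a Monte-Carlo free-energy estimate
#' (hard-sample dataset loss plus `rho` times the Bernoulli KL) is recorded.
#'
#' @param net A [layered_srm()] (typically with `sqrt_fan_in` thresholds).
#' @param dataset A `spike_dataset`.
#' @param prior A [bernoulli_prior()] (scalar logits broadcast).
#' @param cfg A [gs_config()].
#' @param init Optional initial posterior.
#' @param fe_samples Hard samples per free-energy estimate.
#' @return An `svi_fit` with `family = "bernoulli"`.
#' @export
train_bernoulli_vi <- function(net, dataset, prior = bernoulli_prior(),
                               cfg = gs_config(), init = NULL, fe_samples = 2L) {
  stopifnot(inherits(dataset, "spike_dataset"))
  n <- dim(dataset$x)[3]
  if (n == 0L) stop("empty dataset", call. = FALSE)
  shapes <- lapply(init_weights(net, seed = 1L), function(w) w * 0)
  prior <- conform_bernoulli_prior(prior, shapes)
  post <- init %||% bernoulli_posterior(prior$logits0)
  logits <- post$logits
  fe <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(n, cfg$batch_size, cfg$seed + 131L * epoch)
      for (batch in batches) {
        xb <- dataset$x[, , batch, drop = FALSE]
        yb <- one_hot_matrix(dataset$labels[batch], net$n_classes)
        logits <- bernoulli_vi_batch_pass(net, logits, prior, xb, yb, cfg)
      }
      el <- mean(vapply(seq_len(fe_samples), function(s) {
        dataset_loss(net, hard_sample(logits), dataset)
      }, 0))
      fe[epoch] <- el + cfg$rho * bernoulli_kl(bernoulli_posterior(logits), prior)
    }
  })
  structure(list(posterior = bernoulli_posterior(logits), prior = prior,
                 net = net, cfg = cfg, family = "bernoulli",
                 fe_trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                           free_energy = fe)),
            class = "svi_fit")
}

bernoulli_vi_batch_pass <- function(net, logits, prior, xb, yb, cfg) {
  T_steps <- dim(xb)[2]
  n_b <- dim(xb)[3]
  L <- net$n_layers
  states <- lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  prev <- lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  for (t in seq_len(T_steps)) {
    w <- gumbel_sample(logits, cfg)
    g_mu <- vector("list", L)
    pre_now <- matrix(xb[, t, ], nrow = net$layer_sizes[1])
    for (l in seq_len(L)) {
      states[[l]] <- step_filters(states[[l]], pre_now, prev[[l]], net$filters)
      u <- membrane_potential(w[[l]], states[[l]]$syn_traces,
                              if (net$refractory) states[[l]]$ref_traces else NULL)
      sp <- fire(u, net$thresholds[l])
      e <- error_signal_batch(sp, yb, net$readout[[l]])
      ep <- e * post_sensitivity(u, net$thresholds[l])
      g <- layer_grad_step(ep, states[[l]]$syn_traces)$g
      g_mu[[l]] <- grad_estimate(g, w[[l]], logits[[l]], cfg)
      prev[[l]] <- sp
      pre_now <- sp
    }
    logits <- update_logits(logits, g_mu, prior, cfg)
  }
  logits
}
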