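#' Class-balanced random coreset selection
#'
#' Draws, uniformly at random and without replacement, a fixed fraction of
#' each class's examples (rounded half-up per class). The coreset is stored by
#' index into the dataset.
#'
#' @param dataset A `spike_dataset`.
#' @param fraction Fraction of each class to keep, in \[0, 1\].
#' @param seed Integer seed.
#' @return Integer vector of selected example indices.
#' @export
select_coreset <- function(dataset, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (fraction == 0) return(integer(0))
  with_seed(seed, {
    idx_by_class <- split(seq_along(dataset$labels), dataset$labels)
    sort(unlist(lapply(idx_by_class, function(idx) {
      k <- floor(fraction * length(idx) + 0.5)  # round half up
      if (k == 0L) integer(0) else sample(idx, k)
    }), use.names = FALSE))
  })
}

#' Diagonal Fisher information estimate
#'
#' `F = sum_{(x,y) in D} (grad_w L_{x,y}(w))^2` elementwise, where each
#' example's gradient is the surrogate-gradient of its full-sequence loss
#' (local losses accumulated over time, per layer).
#'
#' @param net A [layered_srm()].
#' @param weights Per-layer weight matrices.
#' @param dataset A `spike_dataset`.
#' @param slope Surrogate slope.
#' @return List of nonnegative matrices shaped like `weights`.
#' @export
fim_diag <- function(net, weights, dataset, slope = 1) {
  n <- dim(dataset$x)[3]
  if (n == 0L) stop("empty dataset", call. = FALSE)
  grads <- per_example_grads(net, weights, dataset, slope)
  lapply(seq_len(net$n_layers), function(l) {
    apply(grads[[l]]^2, c(1, 2), sum)
  })
}

# per-example accumulated (over time) gradients: list over layers of
# n_post x n_pre x N arrays
per_example_grads <- function(net, weights, dataset, slope = 1, chunk = 64L) {
  n <- dim(dataset$x)[3]
  out <- lapply(seq_len(net$n_layers), function(l) {
    array(0, c(net$layer_sizes[l + 1L], net$layer_sizes[l], n))
  })
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fwd <- srm_forward(net, dataset$x[, , idx, drop = FALSE], weights)
    yb <- one_hot_matrix(dataset$labels[idx], net$n_classes)
    for (l in seq_len(net$n_layers)) {
      th <- net$thresholds[l]
      for (t in seq_len(dataset$T)) {
        S <- matrix(fwd$spikes[[l]][, t, ], nrow = net$layer_sizes[l + 1L])
        U <- matrix(fwd$potentials[[l]][, t, ], nrow = net$layer_sizes[l + 1L])
        tr <- matrix(fwd$pre_traces[[l]][, t, ], nrow = net$layer_sizes[l])
        ep <- error_signal_batch(S, yb, net$readout[[l]]) *
          post_sensitivity(U, th, slope)
        for (b in seq_along(idx)) {
          out[[l]][, , idx[b]] <- out[[l]][, , idx[b]] + outer(ep[, b], tr[, b])
        }
      }
    }
  }
  out
}

#' Elastic-weight-consolidation state
#'
#' Anchors (weight snapshots after each completed task) and their diagonal
#' Fisher information estimates, plus the regularization strength.
#'
#' @param alpha Regularization strength (>= 0).
#' @return An `ewc_state` with empty anchor/FIM lists.
#' @export
ewc_state <- function(alpha = 1) {
  structure(list(anchors = list(), fims = list(), alpha = alpha),
            class = "ewc_state")
}

#' Quadratic EWC penalty
#'
#' `sum_k (w - w_k)' diag(F_k) (w - w_k)` over all stored anchors.
#'
#' @param w Per-layer weight matrices.
#' @param state An [ewc_state()].
#' @return Nonnegative scalar.
#' @export
ewc_penalty <- function(w, state) {
  if (length(state$anchors) == 0L) return(0)
  sum(vapply(seq_along(state$anchors), function(k) {
    sum(vapply(seq_along(w), function(l) {
      sum(state$fims[[k]][[l]] * (w[[l]] - state$anchors[[k]][[l]])^2)
    }, 0))
  }, 0))
}

# gradient of ewc_penalty w.r.t. w (per layer)
ewc_penalty_grad <- function(w, state) {
  lapply(seq_along(w), function(l) {
    g <- w[[l]] * 0
    for (k in seq_along(state$anchors)) {
      g <- g + 2 * state$fims[[k]][[l]] * (w[[l]] - state$anchors[[k]][[l]])
    }
    g
  })
}

# evaluate accuracy and ECE on every task's test set
eval_stream_tasks <- function(stream, predict_fn, M = 10L) {
  purrr::map_dfr(seq_along(stream$tasks), function(k) {
    test <- stream$tasks[[k]]$test
    rep <- calibration_summary(predict_fn(test), test$labels, M)
    tibble::tibble(task = k, accuracy = rep$accuracy, ece = rep$ece)
  })
}

# Pool a task's training set with the coresets of previous tasks. The
# continual objective sums the *mean* loss of the current dataset and of each
# coreset, so every task term carries equal weight regardless of its size;
# with uniform batches over the pool this is realized by upsampling each
# coreset (with replication) to the size of the current training set.
pool_with_coresets <- function(stream, k, coreset_idx) {
  cur <- stream$tasks[[k]]$train
  parts <- list(cur)
  n_cur <- dim(cur$x)[3]
  if (k > 1L) {
    for (kp in seq_len(k - 1L)) {
      idx <- coreset_idx[[kp]]
      if (length(idx) > 0L) {
        reps <- max(1L, round(n_cur / length(idx)))
        parts <- c(parts, list(dataset_subset(stream$tasks[[kp]]$train,
                                              rep(idx, reps))))
      }
    }
  }
  do.call(dataset_bind, parts)
}

#' Frequentist continual learning with coresets and EWC
#'
#' Trains task-by-task: at task `k` the surrogate-gradient trainer runs on the
#' pool of the current training set and all stored coresets (uniform over the
#' pooled examples), with the quadratic EWC penalty gradient
#' `alpha * 2 * sum_k F_k (w - w_k)` added to every online update. After each
#' task the weights are anchored, the diagonal Fisher information is estimated
#' on that task's training set, and a coreset is drawn. `alpha = 0` with
#' `coreset_fraction = 0` gives the plain sequential-SGD baseline; a single
#' task reduces exactly to offline frequentist training.
#'
#' @param net A [layered_srm()].
#' @param stream A `task_stream`.
#' @param cfg A [train_config()] (applied per task).
#' @param alpha EWC strength.
#' @param coreset_fraction Per-class coreset fraction.
#' @param binary Use straight-through-estimator binary training.
#' @param eval_M Reliability bins for the per-stage evaluation.
#' @return A `continual_fit` with final `weights`, the `ewc` state, coreset
#'   indices, and `metrics` (tibble: stage, task, accuracy, ece).
#' @export
train_ewc <- function(net, stream, cfg = train_config(), alpha = 1,
                      coreset_fraction = 0.1, binary = FALSE, eval_M = 10L) {
  stopifnot(inherits(stream, "task_stream"), length(stream$tasks) >= 1L)
  state <- ewc_state(alpha)
  coreset_idx <- vector("list", length(stream$tasks))
  weights <- NULL
  bw <- NULL
  metrics <- NULL
  for (k in seq_along(stream$tasks)) {
    pooled <- pool_with_coresets(stream, k, coreset_idx)
    if (is.null(weights)) {
      init <- if (binary) binary_weights(init_weights(net, seed = cfg$seed, scale = 0.5))
              else init_weights(net, seed = cfg$seed)
    } else {
      init <- if (binary) bw else weights
    }
    fit <- train_frequentist_ewc(net, pooled, cfg, binary, init, state)
    weights <- fit$weights
    bw <- fit$bw
    state$anchors[[k]] <- weights
    state$fims[[k]] <- fim_diag(net, weights, stream$tasks[[k]]$train,
                                cfg$surrogate_slope)
    coreset_idx[[k]] <- select_coreset(stream$tasks[[k]]$train,
                                       coreset_fraction, seed = cfg$seed + k)
    m <- eval_stream_tasks(stream, function(d) predict_frequentist(net, weights, d),
                           eval_M)
    metrics <- dplyr::bind_rows(metrics, dplyr::mutate(m, stage = k, .before = 1))
  }
  structure(list(weights = weights, latent = if (binary) bw$w_latent,
                 ewc = state, coresets = coreset_idx, net = net, cfg = cfg,
                 binary = binary, metrics = metrics,
                 method = if (alpha > 0) "ewc" else "sgd"),
            class = "continual_fit")
}

# frequentist trainer with an additive EWC penalty gradient on each update
train_frequentist_ewc <- function(net, dataset, cfg, binary, init, state) {
  n <- dim(dataset$x)[3]
  bw <- if (binary) init else NULL
  weights <- if (binary) bw$w else init
  for (epoch in seq_len(cfg$epochs)) {
    batches <- epoch_batches(n, cfg$batch_size, cfg$seed + epoch)
    for (batch in batches) {
      xb <- dataset$x[, , batch, drop = FALSE]
      yb <- one_hot_matrix(dataset$labels[batch], net$n_classes)
      out <- ewc_batch_pass(net, weights, bw, xb, yb, cfg, binary, state)
      weights <- out$weights
      bw <- out$bw
    }
  }
  list(weights = weights, bw = bw)
}

ewc_batch_pass <- function(net, weights, bw, xb, yb, cfg, binary, state) {
  T_steps <- dim(xb)[2]
  n_b <- dim(xb)[3]
  L <- net$n_layers
  states <- lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  prev <- lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  has_penalty <- state$alpha > 0 && length(state$anchors) > 0L
  for (t in seq_len(T_steps)) {
    pen <- if (has_penalty) ewc_penalty_grad(weights, state)
    pre_now <- matrix(xb[, t, ], nrow = net$layer_sizes[1])
    for (l in seq_len(L)) {
      states[[l]] <- step_filters(states[[l]], pre_now, prev[[l]], net$filters)
      u <- membrane_potential(weights[[l]], states[[l]]$syn_traces,
                              if (net$refractory) states[[l]]$ref_traces else NULL)
      s <- fire(u, net$thresholds[l])
      e <- error_signal_batch(s, yb, net$readout[[l]])
      ep <- e * post_sensitivity(u, net$thresholds[l], cfg$surrogate_slope)
      g <- layer_grad_step(ep, states[[l]]$syn_traces)$g
      if (has_penalty) g <- g + state$alpha * pen[[l]] / T_steps
      if (binary) {
        bw$w_latent[[l]] <- bw$w_latent[[l]] - cfg$eta * g
        weights[[l]] <- sign_ste(bw$w_latent[[l]])
      } else {
        weights[[l]] <- weights[[l]] - cfg$eta * g
      }
      prev[[l]] <- s
      pre_now <- s
    }
  }
  if (binary) bw$w <- weights
  list(weights = weights, bw = bw)
}

#' Biologically inspired plasticity state
#'
#' Per-synapse metaplasticity counters `nu`, reference weights `w_ref`, and
#' the rule's rates: the metaplasticity increment `delta_nu` (applied when
#' both pre- and post-synaptic firing rates exceed `rate_threshold`), the
#' reference-tracking rate `kappa`, and the heterosynaptic decay `gamma`.
#'
#' @param weights Per-layer weight matrices (template for shapes).
#' @param delta_nu Metaplasticity step.
#' @param kappa Reference-weight tracking rate in (0, 1\].
#' @param gamma Heterosynaptic decay rate (>= 0).
#' @param rate_threshold Firing-rate threshold (spikes/step).
#' @return A `bio_plasticity_state`.
#' @export
bio_plasticity_state <- function(weights, delta_nu = 0.1, kappa = 0.01,
                                 gamma = 0.01, rate_threshold = 0.1) {
  stopifnot(kappa > 0, kappa <= 1, gamma >= 0, delta_nu >= 0)
  structure(list(nu = lapply(weights, function(w) w * 0),
                 w_ref = lapply(weights, function(w) w * 0),
                 delta_nu = delta_nu, kappa = kappa, gamma = gamma,
                 rate_threshold = rate_threshold),
            class = "bio_plasticity_state")
}

#' Metaplasticity and reference-weight update
#'
#' `nu` increases by `delta_nu` for synapses whose pre- and post-synaptic
#' firing rates both exceed the rate threshold; the reference weight tracks
#' the current weight as `w_ref <- w_ref + kappa * (w - w_ref)` at every step.
#'
#' @param state A [bio_plasticity_state()].
#' @param pre_rate Pre-synaptic firing rates (one per pre neuron, per layer
#'   list).
#' @param post_rate Post-synaptic firing rates (per layer list).
#' @param w Current per-layer weights.
#' @return The updated state.
#' @export
bio_state_update <- function(state, pre_rate, post_rate, w) {
  for (l in seq_along(w)) {
    gate <- outer(post_rate[[l]] > state$rate_threshold,
                  pre_rate[[l]] > state$rate_threshold)
    state$nu[[l]] <- state$nu[[l]] + state$delta_nu * gate
    state$w_ref[[l]] <- state$w_ref[[l]] + state$kappa * (w[[l]] - state$w_ref[[l]])
  }
  state
}

#' Biologically inspired online weight update
#'
#' `w <- w - exp(-|nu * w|) * (eta * e * s_j * sigma'(u - theta) +
#' gamma * (w - w_ref) * s_i)`: a three-factor update gated by the
#' pre-synaptic spike, damped multiplicatively by metaplasticity, plus a
#' heterosynaptic drift toward the reference weight gated by the
#' post-synaptic spike.
#'
#' @param w Weight matrix (post x pre).
#' @param state A [bio_plasticity_state()] (single-layer slices `nu`,
#'   `w_ref`).
#' @param nu,w_ref Metaplasticity and reference matrices for this layer.
#' @param e_it Post-synaptic error signals (length n_post).
#' @param s_j_t Pre-synaptic spikes (length n_pre).
#' @param s_i_t Post-synaptic spikes (length n_post).
#' @param u_it Post-synaptic membrane potentials.
#' @param threshold Firing threshold.
#' @param eta Learning rate.
#' @param gamma Heterosynaptic decay rate.
#' @param slope Surrogate slope.
#' @return Updated weight matrix.
#' @export
bio_weight_update <- function(w, nu, w_ref, e_it, s_j_t, s_i_t, u_it, threshold,
                              eta, gamma, slope = 1) {
  damp <- exp(-abs(nu * w))
  grad_term <- eta * outer(e_it * post_sensitivity(u_it, threshold, slope), s_j_t)
  drift_term <- gamma * (w - w_ref) * s_i_t  # column-recycled over pre synapses
  w - damp * (grad_term + drift_term)
}

#' Continual learning with the biologically inspired rule
#'
#' Sequential task training where every online update follows
#' [bio_weight_update()] and the metaplasticity/reference state advances with
#' [bio_state_update()] (firing rates are running means over the current
#' presentation, averaged across the mini-batch).
#'
#' @inheritParams train_ewc
#' @param bio Optional pre-built [bio_plasticity_state()].
#' @return A `continual_fit` with `method = "bio"`.
#' @export
train_continual_bio <- function(net, stream, cfg = train_config(),
                                bio = NULL, eval_M = 10L) {
  stopifnot(inherits(stream, "task_stream"))
  weights <- init_weights(net, seed = cfg$seed)
  if (is.null(bio)) bio <- bio_plasticity_state(weights)
  metrics <- NULL
  for (k in seq_along(stream$tasks)) {
    dataset <- stream$tasks[[k]]$train
    n <- dim(dataset$x)[3]
    for (epoch in seq_len(cfg$epochs)) {
      batches <- epoch_batches(n, cfg$batch_size, cfg$seed + 977L * epoch + k)
      for (batch in batches) {
        xb <- dataset$x[, , batch, drop = FALSE]
        yb <- one_hot_matrix(dataset$labels[batch], net$n_classes)
        out <- bio_batch_pass(net, weights, bio, xb, yb, cfg)
        weights <- out$weights
        bio <- out$bio
      }
    }
    m <- eval_stream_tasks(stream, function(d) predict_frequentist(net, weights, d),
                           eval_M)
    metrics <- dplyr::bind_rows(metrics, dplyr::mutate(m, stage = k, .before = 1))
  }
  structure(list(weights = weights, bio = bio, net = net, cfg = cfg,
                 metrics = metrics, method = "bio"),
            class = "continual_fit")
}

bio_batch_pass <- function(net, weights, bio, xb, yb, cfg) {
  T_steps <- dim(xb)[2]
  n_b <- dim(xb)[3]
  L <- net$n_layers
  states <- lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  prev <- lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  spike_sums <- lapply(seq_len(L + 1L), function(l) {
    numeric(if (l == 1L) net$layer_sizes[1] else net$layer_sizes[l])
  })
  for (t in seq_len(T_steps)) {
    pre_now <- matrix(xb[, t, ], nrow = net$layer_sizes[1])
    spike_sums[[1]] <- spike_sums[[1]] + rowMeans(pre_now)
    for (l in seq_len(L)) {
      states[[l]] <- step_filters(states[[l]], pre_now, prev[[l]], net$filters)
      u <- membrane_potential(weights[[l]], states[[l]]$syn_traces,
                              if (net$refractory) states[[l]]$ref_traces else NULL)
      s <- fire(u, net$thresholds[l])
      e <- error_signal_batch(s, yb, net$readout[[l]])
      # batch-averaged spikes and errors drive the single online update
      weights[[l]] <- bio_weight_update(
        weights[[l]], bio$nu[[l]], bio$w_ref[[l]],
        rowMeans(e), rowMeans(pre_now), rowMeans(s), rowMeans(u),
        net$thresholds[l], cfg$eta, bio$gamma, cfg$surrogate_slope)
      spike_sums[[l + 1L]] <- spike_sums[[l + 1L]] + rowMeans(s)
      prev[[l]] <- s
      pre_now <- s
    }
    rates <- lapply(spike_sums, function(x) x / t)
    bio <- bio_state_update(bio, rates[seq_len(L)], rates[-1L], weights)
  }
  list(weights = weights, bio = bio)
}

#' Bayesian continual learning with a Gaussian posterior
#'
#' Chains the Gaussian variational trainer across tasks: at task `k` the prior
#' is the posterior snapshot from task `k - 1` (bit-identical), mini-batches
#' are drawn uniformly from the pool of the current training set and all
#' stored coresets, and a class-balanced coreset is drawn after each task.
#' Task 1 with `prior0` is identical to offline [train_gaussian_vi()] on the
#' first dataset.
#'
#' @param net A [layered_srm()].
#' @param stream A `task_stream`.
#' @param prior0 Initial [gaussian_prior()].
#' @param cfg A [vi_config()] (applied per task).
#' @param coreset_fraction Per-class coreset fraction.
#' @param n_s Committee size for the per-stage evaluation.
#' @param eval_M Reliability bins for the evaluation.
#' @return A `continual_fit` with per-task `posteriors`, final `posterior`,
#'   coreset indices, `metrics`, and a `precision_trace` tibble (per-task mean
#'   precision, a logged diagnostic of synaptic consolidation).
#' @export
train_continual_gaussian <- function(net, stream, prior0 = gaussian_prior(),
                                     cfg = vi_config(), coreset_fraction = 0.1,
                                     n_s = 10L, eval_M = 10L) {
  stopifnot(inherits(stream, "task_stream"))
  coreset_idx <- vector("list", length(stream$tasks))
  posteriors <- vector("list", length(stream$tasks))
  priors <- vector("list", length(stream$tasks))
  prior <- prior0
  post <- NULL
  metrics <- NULL
  prec <- numeric(length(stream$tasks))
  for (k in seq_along(stream$tasks)) {
    pooled <- pool_with_coresets(stream, k, coreset_idx)
    priors[[k]] <- prior
    fit <- train_gaussian_vi(net, pooled, prior, cfg, init = post)
    post <- fit$posterior
    posteriors[[k]] <- post
    prior <- gaussian_prior(m0 = post$m, p0 = post$p)  # posterior-as-prior chain
    coreset_idx[[k]] <- select_coreset(stream$tasks[[k]]$train,
                                       coreset_fraction, seed = cfg$seed + k)
    prec[k] <- mean(unlist(post$p))
    m <- eval_stream_tasks(stream, function(d) {
      predict_bayesian(net, post, d, n_s = n_s, mode = "committee",
                       seed = cfg$seed + 7L)
    }, eval_M)
    metrics <- dplyr::bind_rows(metrics, dplyr::mutate(m, stage = k, .before = 1))
  }
  structure(list(posterior = post, posteriors = posteriors, priors = priors,
                 coresets = coreset_idx, net = net, cfg = cfg,
                 metrics = metrics, method = "bayes-gauss",
                 precision_trace = tibble::tibble(task = seq_along(prec),
                                                  mean_precision = prec)),
            class = "continual_fit")
}

#' Bayesian continual learning with a Bernoulli posterior
#'
#' The binary-synapse counterpart of [train_continual_gaussian()]: the logit
#' update at task `k` uses the previous task's logits as the prior, and
#' batches pool the current data with the stored coresets.
#'
#' @inheritParams train_continual_gaussian
#' @param prior0 Initial [bernoulli_prior()].
#' @param cfg A [gs_config()].
#' @return A `continual_fit` with `method = "bayes-bern"`.
#' @export
train_continual_bernoulli <- function(net, stream, prior0 = bernoulli_prior(),
                                      cfg = gs_config(), coreset_fraction = 0.1,
                                      n_s = 10L, eval_M = 10L) {
  stopifnot(inherits(stream, "task_stream"))
  coreset_idx <- vector("list", length(stream$tasks))
  posteriors <- vector("list", length(stream$tasks))
  priors <- vector("list", length(stream$tasks))
  prior <- prior0
  post <- NULL
  metrics <- NULL
  for (k in seq_along(stream$tasks)) {
    pooled <- pool_with_coresets(stream, k, coreset_idx)
    priors[[k]] <- prior
    fit <- train_bernoulli_vi(net, pooled, prior, cfg, init = post)
    post <- fit$posterior
    posteriors[[k]] <- post
    prior <- bernoulli_prior(post$logits)
    coreset_idx[[k]] <- select_coreset(stream$tasks[[k]]$train,
                                       coreset_fraction, seed = cfg$seed + k)
    m <- eval_stream_tasks(stream, function(d) {
      predict_bayesian(net, post, d, n_s = n_s, mode = "committee",
                       seed = cfg$seed + 7L)
    }, eval_M)
    metrics <- dplyr::bind_rows(metrics, dplyr::mutate(m, stage = k, .before = 1))
  }
  structure(list(posterior = post, posteriors = posteriors, priors = priors,
                 coresets = coreset_idx, net = net, cfg = cfg,
                 metrics = metrics, method = "bayes-bern"),
            class = "continual_fit")
}

#' @export
print.continual_fit <- function(x, ...) {
  final <- dplyr::filter(x$metrics, .data$stage == max(.data$stage))
  cat(sprintf("<continual_fit [%s]: %d tasks, final mean accuracy %.3f, mean ECE %.3f>\n",
              x$method, max(x$metrics$stage), mean(final$accuracy),
              mean(final$ece)))
  invisible(x)
}
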