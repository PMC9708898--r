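#' Frequentist training configuration
#'
#' @param eta Learning rate (> 0).
#' @param batch_size Mini-batch size (each element runs as an independent
#'   network replica; updates use the batch-averaged gradient once per
#'   time-step).
#' @param epochs Number of passes over the dataset.
#' @param surrogate_slope Slope of the sigmoid surrogate used in place of the
#'   threshold derivative.
#' @param seed Integer seed (shuffling; also the default for any sampling the
#'   trainer performs).
#' @return A `train_config` object.
#' @export
train_config <- function(eta = 0.05, batch_size = 16L, epochs = 10L,
                         surrogate_slope = 1, seed = 1L) {
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be at least 1", call. = FALSE)
  structure(list(eta = eta, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), surrogate_slope = surrogate_slope,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Per-layer local loss
#'
#' The cross-entropy between the one-hot target at time `t` and the softmax of
#' the layer's spikes projected through its fixed random read-out matrix:
#' `-sum_m y_m * log Softmax_m(B_l s_t)`. Every layer, including the read-out
#' layer, is scored this way; layers learn only from their own local loss.
#'
#' @param spikes_l Spike vector of layer `l` at one time-step.
#' @param target_t One-hot target column (length C).
#' @param B_l Fixed `C x n_l` read-out matrix.
#' @return Nonnegative scalar loss.
#' @export
local_loss <- function(spikes_l, target_t, B_l) {
  if (!isTRUE(all.equal(sum(target_t), 1)) || any(target_t < 0) ||
      sum(target_t == 1) != 1L) {
    stop("`target_t` must be a one-hot vector", call. = FALSE)
  }
  p <- softmax(as.vector(B_l %*% spikes_l))
  -sum(target_t * log(p))
}

#' Per-neuron error signal of the local loss
#'
#' Analytic derivative of [local_loss()] with respect to the layer's spike
#' vector: `e_i = sum_m (Softmax_m(B_l s) - y_m) * B_l[m, i]`.
#'
#' @inheritParams local_loss
#' @return Numeric vector, one entry per neuron in the layer.
#' @export
error_signal <- function(spikes_l, target_t, B_l) {
  p <- softmax(as.vector(B_l %*% spikes_l))
  as.vector(crossprod(B_l, p - target_t))
}

# batched versions: S (n_l x B), Y (C x B). Returns loss vector (B) and error
# matrix (n_l x B).
local_loss_batch <- function(S, Y, B_l) {
  p <- softmax(B_l %*% S)
  -colSums(Y * log(pmax(p, 1e-300)))
}

error_signal_batch <- function(S, Y, B_l) {
  p <- softmax(B_l %*% S)
  crossprod(B_l, p - Y)
}

#' Three-factor surrogate gradient
#'
#' The weight gradient of the local loss decomposes into an error signal, a
#' post-synaptic sensitivity, and a pre-synaptic trace:
#' `e_it * sigma'(slope * (u_it - threshold)) * pre_trace`. The post-synaptic
#' factor alone is exposed as [post_sensitivity()].
#'
#' @param e_it Error signal of the post-synaptic neuron.
#' @param u_it Membrane potential of the post-synaptic neuron.
#' @param threshold Firing threshold.
#' @param pre_trace Filtered trace of the pre-synaptic neuron.
#' @param slope Sigmoid surrogate slope.
#' @return The gradient contribution (elementwise over the inputs).
#' @export
surrogate_gradient <- function(e_it, u_it, threshold, pre_trace, slope = 1) {
  e_it * post_sensitivity(u_it, threshold, slope) * pre_trace
}

#' @rdname surrogate_gradient
#' @export
post_sensitivity <- function(u_it, threshold, slope = 1) {
  sigmoid_prime(slope * (u_it - threshold))
}

#' Mini-batch stochastic gradient step
#'
#' `w <- w - eta * mean(batch_grads)`.
#'
#' @param w Weights (any numeric shape).
#' @param batch_grads A list of per-example gradients shaped like `w`, or a
#'   single already-averaged gradient.
#' @param eta Learning rate.
#' @return Updated weights.
#' @export
sgd_step <- function(w, batch_grads, eta) {
  g <- average_grads(batch_grads)
  w - eta * g
}

average_grads <- function(batch_grads) {
  if (is.list(batch_grads)) {
    if (length(batch_grads) == 0L) stop("empty gradient batch", call. = FALSE)
    Reduce(`+`, batch_grads) / length(batch_grads)
  } else {
    batch_grads
  }
}

#' Binary weights with latent real-valued companions
#'
#' Straight-through-estimator state: the forward weights are
#' `w = sign(w_latent)` with `sign(0) = +1`; gradients update the latent
#' weights.
#'
#' @param w_latent Real-valued latent weights (matrix or list of matrices).
#' @return A `binary_weights` object with elements `w` and `w_latent`.
#' @export
binary_weights <- function(w_latent) {
  structure(list(w = sign_ste(w_latent), w_latent = w_latent),
            class = "binary_weights")
}

# sign with sign(0) = +1, mapped over lists
sign_ste <- function(x) {
  if (is.list(x)) return(lapply(x, sign_ste))
  ifelse(x >= 0, 1, -1) * 1
}

#' Straight-through-estimator update
#'
#' Applies the SGD rule to the latent weights using gradients evaluated at the
#' binarized weights, then re-binarizes: `w = sign(w_latent)`, `sign(0) = +1`.
#'
#' @param bw A [binary_weights()] object.
#' @param batch_grads Per-example gradients (list) or averaged gradient,
#'   evaluated at `bw$w`.
#' @param eta Learning rate.
#' @return Updated `binary_weights`.
#' @export
ste_step <- function(bw, batch_grads, eta) {
  binary_weights(sgd_step(bw$w_latent, batch_grads, eta))
}

# Per-layer batch-averaged gradient (and optionally the batch average of the
# per-example squared gradient) of the local losses at one time-step.
# ep: e * post factor (n_post x B); tr: pre traces (n_pre x B).
layer_grad_step <- function(ep, tr, sq = FALSE) {
  n_b <- ncol(ep)
  g <- (ep %*% t(tr)) / n_b
  if (!sq) return(list(g = g))
  list(g = g, sq = ((ep^2) %*% t(tr^2)) / n_b)
}

# shuffled batch index list for one epoch
epoch_batches <- function(n, batch_size, seed) {
  idx <- with_seed(seed, sample.int(n))
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Frequentist surrogate-gradient training
#'
#' Online DECOLLE-style training of a layered SRM: at every time-step each
#' layer computes its local loss against the one-hot target, derives the
#' three-factor gradient (error signal x post-synaptic sensitivity x
#' pre-synaptic trace), and applies the batch-averaged SGD update immediately.
#' Gradients never propagate across layers or across time. With
#' `binary = TRUE` the network runs with `sign(w_latent)` weights and the
#' straight-through estimator updates the latent weights.
#'
#' @param net A [layered_srm()].
#' @param dataset A `spike_dataset`.
#' @param cfg A [train_config()].
#' @param binary Train binary +-1 synapses via the straight-through estimator.
#' @param init Optional initial weights (list of matrices, or
#'   [binary_weights()] when `binary`).
#' @return An `snn_fit` object: `weights` (binary forward weights when
#'   `binary`), `latent` (latent weights, binary mode only), `loss_trace`
#'   (tibble epoch/loss), plus the net and config.
#' @export
train_frequentist <- function(net, dataset, cfg = train_config(), binary = FALSE,
                              init = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  n <- dim(dataset$x)[3]
  if (n == 0L) stop("empty dataset", call. = FALSE)
  C <- net$n_classes
  if (is.null(init)) {
    init <- if (binary) binary_weights(init_weights(net, seed = cfg$seed, scale = 0.5))
            else init_weights(net, seed = cfg$seed)
  }
  bw <- if (binary) init else NULL
  weights <- if (binary) bw$w else init
  check_weight_shapes(net, weights)

  losses <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    batches <- epoch_batches(n, cfg$batch_size, cfg$seed + epoch)
    epoch_loss <- 0
    for (batch in batches) {
      xb <- dataset$x[, , batch, drop = FALSE]
      yb <- one_hot_matrix(dataset$labels[batch], C)
      out <- frequentist_batch_pass(net, weights, bw, xb, yb, cfg, binary)
      weights <- out$weights
      bw <- out$bw
      epoch_loss <- epoch_loss + out$loss_sum
    }
    losses[epoch] <- epoch_loss / n
  }
  structure(list(weights = weights, latent = if (binary) bw$w_latent,
                 net = net, cfg = cfg, binary = binary,
                 loss_trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                             loss = losses)),
            class = "snn_fit")
}

# one online pass over a mini-batch: simulate all T steps, updating weights at
# every step. Returns updated weights and the summed per-example loss.
frequentist_batch_pass <- function(net, weights, bw, xb, yb, cfg, binary) {
  T_steps <- dim(xb)[2]
  n_b <- dim(xb)[3]
  L <- net$n_layers
  states <- lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  prev <- lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  loss_sum <- 0
  for (t in seq_len(T_steps)) {
    pre_now <- matrix(xb[, t, ], nrow = net$layer_sizes[1])
    for (l in seq_len(L)) {
      states[[l]] <- step_filters(states[[l]], pre_now, prev[[l]], net$filters)
      u <- membrane_potential(weights[[l]], states[[l]]$syn_traces,
                              if (net$refractory) states[[l]]$ref_traces else NULL)
      s <- fire(u, net$thresholds[l])
      e <- error_signal_batch(s, yb, net$readout[[l]])
      loss_sum <- loss_sum + sum(local_loss_batch(s, yb, net$readout[[l]]))
      ep <- e * post_sensitivity(u, net$thresholds[l], cfg$surrogate_slope)
      g <- layer_grad_step(ep, states[[l]]$syn_traces)$g
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
  list(weights = weights, bw = bw, loss_sum = loss_sum)
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf("<snn_fit: %s synapses, %d epochs, final loss %.4f>\n",
              if (x$binary) "binary" else "real-valued",
              nrow(x$loss_trace), utils::tail(x$loss_trace$loss, 1)))
  invisible(x)
}
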