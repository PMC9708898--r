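#' Synaptic and somatic filter time constants
#'
#' The discrete-time spike response model filters pre-synaptic spikes with the
#' alpha-function kernel `alpha_t = exp(-t/tau_mem) - exp(-t/tau_syn)` and the
#' neuron's own spikes with the exponentially decaying refractory kernel
#' `exp(-t/tau_ref)` (subtracted from the membrane potential, implementing
#' hyperpolarizing self-feedback). Time constants are expressed in simulation
#' steps.
#'
#' @param tau_mem Membrane time constant (steps), > 0.
#' @param tau_syn Synaptic time constant (steps), > 0 and different from
#'   `tau_mem` (otherwise the alpha kernel degenerates to zero).
#' @param tau_ref Refractory time constant (steps), > 0.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(tau_mem = 20, tau_syn = 5, tau_ref = 10) {
  stopifnot_scalar_number(tau_mem, "tau_mem")
  stopifnot_scalar_number(tau_syn, "tau_syn")
  stopifnot_scalar_number(tau_ref, "tau_ref")
  if (tau_mem <= 0 || tau_syn <= 0 || tau_ref <= 0) {
    stop("all time constants must be strictly positive", call. = FALSE)
  }
  if (tau_mem == tau_syn) {
    stop("`tau_mem` must differ from `tau_syn` (alpha kernel would vanish)",
         call. = FALSE)
  }
  structure(list(tau_mem = tau_mem, tau_syn = tau_syn, tau_ref = tau_ref),
            class = "filter_params")
}

#' Closed-form filter kernels
#'
#' `alpha_kernel()` is the synaptic impulse response
#' `exp(-t/tau_mem) - exp(-t/tau_syn)`; `beta_kernel()` is the magnitude
#' `exp(-t/tau_ref)` of the refractory response. Both are defined for lags
#' `t >= 1` (a spike affects traces only from the following step).
#'
#' @param t Integer lag(s), >= 0; the kernels are zero at `t = 0`.
#' @param filters A [filter_params()] object.
#' @return Numeric vector of kernel values.
#' @export
alpha_kernel <- function(t, filters) {
  ifelse(t <= 0, 0, exp(-t / filters$tau_mem) - exp(-t / filters$tau_syn))
}

#' @rdname alpha_kernel
#' @export
beta_kernel <- function(t, filters) {
  ifelse(t <= 0, 0, exp(-t / filters$tau_ref))
}

#' Binary spike raster
#'
#' A spike raster is a binary matrix with one row per neuron and one column per
#' time-step; entry 1 marks a spike. This constructor validates and tags a
#' matrix; all simulator entry points accept plain binary matrices too.
#'
#' @param values Binary matrix (neurons x time-steps).
#' @return The validated matrix with class `spike_raster`.
#' @export
spike_raster <- function(values) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) {
    stop("spike raster entries must all be 0 or 1", call. = FALSE)
  }
  structure(values, class = c("spike_raster", class(values)))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster: %d neurons x %d steps, %.3f mean rate>\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Per-layer firing thresholds
#'
#' Three conventions are offered: `"unit"` (threshold 1 per layer, the
#' floating-point default), `"sqrt_fan_in"` (the square root of each layer's
#' fan-in, suited to binary +-1 synapses), and `"fixed_point"` (threshold 64,
#' emulating fixed-precision hardware deployments).
#'
#' @param layer_sizes Integer vector of layer sizes, input layer first.
#' @param mode One of `"unit"`, `"sqrt_fan_in"`, `"fixed_point"`.
#' @return Numeric vector with one threshold per trainable layer.
#' @export
srm_thresholds <- function(layer_sizes, mode = c("unit", "sqrt_fan_in", "fixed_point")) {
  mode <- match.arg(mode)
  n_layers <- length(layer_sizes) - 1L
  switch(mode,
    unit = rep(1, n_layers),
    sqrt_fan_in = sqrt(layer_sizes[-length(layer_sizes)]),
    fixed_point = rep(64, n_layers)
  )
}

#' Layered spike-response-model network
#'
#' Defines a feedforward layered SRM: layer sizes (the first entry is the
#' number of exogenous input signals, the last is the read-out layer), one
#' firing threshold per trainable layer, shared filter time constants, and one
#' fixed random read-out matrix `B_l` (`n_classes` x layer size, i.i.d.
#' standard normal) per trainable layer. Read-out matrices are generated once
#' from `readout_seed` and never trained; they project each layer's spikes to
#' class scores for the local losses and, at the final layer, for prediction.
#'
#' @param layer_sizes Integer vector, input size first, read-out layer last.
#' @param n_classes Number of classes C.
#' @param thresholds Numeric vector of per-layer thresholds (> 0); default
#'   [srm_thresholds()] with `threshold_mode`.
#' @param threshold_mode Passed to [srm_thresholds()] when `thresholds` is NULL.
#' @param filters A [filter_params()] object.
#' @param readout_seed Integer seed for the fixed read-out matrices.
#' @param refractory Logical; include the refractory self-feedback term.
#' @return An object of class `layered_srm`.
#' @export
layered_srm <- function(layer_sizes, n_classes, thresholds = NULL,
                        threshold_mode = "unit", filters = filter_params(),
                        readout_seed = 1L, refractory = TRUE) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("`layer_sizes` needs an input layer and at least one trainable layer",
         call. = FALSE)
  }
  n_layers <- length(layer_sizes) - 1L
  if (is.null(thresholds)) thresholds <- srm_thresholds(layer_sizes, threshold_mode)
  if (length(thresholds) != n_layers || any(thresholds <= 0)) {
    stop("`thresholds` must supply one positive value per trainable layer",
         call. = FALSE)
  }
  stopifnot(inherits(filters, "filter_params"))
  readout <- with_seed(readout_seed, lapply(seq_len(n_layers), function(l) {
    matrix(stats::rnorm(n_classes * layer_sizes[l + 1L]),
           nrow = n_classes, ncol = layer_sizes[l + 1L])
  }))
  structure(list(
    layer_sizes = layer_sizes,
    n_layers = n_layers,
    n_classes = as.integer(n_classes),
    thresholds = as.numeric(thresholds),
    filters = filters,
    readout = readout,
    readout_seed = as.integer(readout_seed),
    refractory = isTRUE(refractory)
  ), class = "layered_srm")
}

#' @export
print.layered_srm <- function(x, ...) {
  cat(sprintf("<layered_srm: %s, C=%d, theta=(%s), tau=(%g,%g,%g)%s>\n",
              paste(x$layer_sizes, collapse = "-"), x$n_classes,
              paste(signif(x$thresholds, 3), collapse = ","),
              x$filters$tau_mem, x$filters$tau_syn, x$filters$tau_ref,
              if (x$refractory) "" else ", no refractory"))
  invisible(x)
}

#' Initialize synaptic weights for a layered SRM
#'
#' Real-valued weights are drawn i.i.d. normal with standard deviation
#' `scale/sqrt(fan-in)` per layer; binary weights are drawn uniformly from
#' \{+1, -1\}.
#'
#' @param net A [layered_srm()].
#' @param seed Integer seed.
#' @param scale Scale multiplier for real-valued initialization.
#' @param binary Draw +-1 weights instead.
#' @return List of weight matrices, one per trainable layer
#'   (post-synaptic x pre-synaptic).
#' @export
init_weights <- function(net, seed = 1L, scale = 1, binary = FALSE) {
  with_seed(seed, lapply(seq_len(net$n_layers), function(l) {
    n_pre <- net$layer_sizes[l]
    n_post <- net$layer_sizes[l + 1L]
    if (binary) {
      matrix(sample(c(-1, 1), n_post * n_pre, replace = TRUE), n_post, n_pre)
    } else {
      matrix(stats::rnorm(n_post * n_pre, sd = scale / sqrt(n_pre)), n_post, n_pre)
    }
  }))
}

#' Fresh filter state for one layer
#'
#' Holds the two-exponential synaptic accumulators for the layer's
#' pre-synaptic input, the refractory accumulator for its own spikes, the most
#' recent membrane potentials, and the step counter. All traces start at zero.
#'
#' @param n_pre,n_post Pre- and post-synaptic population sizes.
#' @param n_batch Number of parallel network replicas (mini-batch size).
#' @return An object of class `srm_state`.
#' @export
new_srm_state <- function(n_pre, n_post, n_batch = 1L) {
  z_pre <- matrix(0, n_pre, n_batch)
  z_post <- matrix(0, n_post, n_batch)
  structure(list(
    acc_mem = z_pre, acc_syn = z_pre, syn_traces = z_pre,
    ref_traces = z_post, potentials = z_post, t = 0L
  ), class = "srm_state")
}

#' Advance the synaptic and refractory filters by one step
#'
#' Updates the causal convolutions: the synaptic trace is computed with the
#' two-exponential recursion `a = lambda_mem * a + s`,
#' `b = lambda_syn * b + s`, `trace = a - b` fed with the *current* step's
#' pre-synaptic spikes (the alpha kernel vanishes at lag zero, so a spike first
#' contributes at the next step); the refractory trace is the strictly causal
#' geometric filter `r_new = lambda_ref * (r + s_post_prev)` of the neuron's
#' own spikes from the previous step.
#'
#' @param state An [new_srm_state()] object.
#' @param spikes_pre Pre-synaptic spikes of the current step
#'   (vector or `n_pre x n_batch` matrix; real values allowed in relaxed mode).
#' @param spikes_post_prev Post-synaptic spikes emitted at the previous step.
#' @param filters A [filter_params()].
#' @return The advanced `srm_state`.
#' @export
step_filters <- function(state, spikes_pre, spikes_post_prev, filters) {
  lam_m <- exp(-1 / filters$tau_mem)
  lam_s <- exp(-1 / filters$tau_syn)
  lam_r <- exp(-1 / filters$tau_ref)
  state$acc_mem <- lam_m * state$acc_mem + spikes_pre
  state$acc_syn <- lam_s * state$acc_syn + spikes_pre
  state$syn_traces <- state$acc_mem - state$acc_syn
  state$ref_traces <- lam_r * (state$ref_traces + spikes_post_prev)
  state$t <- state$t + 1L
  state
}

#' Membrane potential from weights and traces
#'
#' `u = W %*% syn_traces - ref_traces`: the weighted sum of filtered
#' pre-synaptic activity minus the refractory trace of the neuron's own spikes.
#'
#' @param weights Weight matrix (post x pre).
#' @param syn_traces Pre-synaptic trace vector or matrix (pre x batch).
#' @param ref_traces Refractory traces (post x batch) or NULL for none.
#' @return Membrane potentials (post x batch matrix).
#' @export
membrane_potential <- function(weights, syn_traces, ref_traces = NULL) {
  if (!is.matrix(syn_traces)) syn_traces <- matrix(syn_traces, ncol = 1L)
  if (ncol(weights) != nrow(syn_traces)) {
    stop("weight matrix columns must match the number of pre-synaptic traces",
         call. = FALSE)
  }
  u <- weights %*% syn_traces
  if (!is.null(ref_traces)) u <- u - ref_traces
  u
}

#' Spike emission
#'
#' Heaviside threshold with the inclusive boundary convention: a neuron fires
#' when its membrane potential reaches or exceeds the threshold
#' (`Theta(0) = 1`).
#'
#' @param u Membrane potentials.
#' @param threshold Firing threshold.
#' @return Binary values of the same shape as `u`.
#' @export
fire <- function(u, threshold) {
  (u >= threshold) + 0
}

# sigma(slope * (u - threshold)): real-valued stand-in for fire() used by the
# relaxed (fully differentiable) network copy.
fire_relaxed <- function(u, threshold, slope = 1) {
  sigmoid(slope * (u - threshold))
}

# normalize input to an n_in x T x B array
as_input_array <- function(input, n_in) {
  if (is.list(input)) input <- simplify2array(input)
  if (is.matrix(input)) input <- array(input, c(nrow(input), ncol(input), 1L))
  if (length(dim(input)) != 3L || dim(input)[1] != n_in) {
    stop("input must be an n_in x T (x batch) spike array matching the input layer",
         call. = FALSE)
  }
  input
}

#' Deterministic forward pass through a layered SRM
#'
#' Simulates all layers over `T` steps for one input raster or a batch of
#' rasters. The pass is strictly causal: a spike emitted at step `t` first
#' affects downstream potentials at step `t + 1`. With `relaxed = TRUE` the
#' threshold function is replaced throughout by the sigmoid surrogate
#' `sigma(slope * (u - theta))` and all "spikes" are real-valued; this smooth
#' copy of the network is what finite-difference checks of the surrogate
#' gradients differentiate.
#'
#' @param net A [layered_srm()].
#' @param input Spike raster (`n_in x T` matrix) or batch array
#'   (`n_in x T x B`).
#' @param weights List of per-layer weight matrices (post x pre).
#' @param relaxed Replace the hard threshold by the sigmoid surrogate.
#' @param slope Sigmoid slope in relaxed mode.
#' @return A list of class `srm_forward` with per-layer lists `spikes`,
#'   `potentials` (`n_l x T x B` arrays) and `pre_traces`
#'   (`n_(l-1) x T x B` arrays of the filtered pre-synaptic activity each layer
#'   saw), plus `T` and `n_batch`.
#' @export
srm_forward <- function(net, input, weights, relaxed = FALSE, slope = 1) {
  x <- as_input_array(input, net$layer_sizes[1])
  T_steps <- dim(x)[2]
  n_b <- dim(x)[3]
  L <- net$n_layers
  check_weight_shapes(net, weights)

  states <- lapply(seq_len(L), function(l) {
    new_srm_state(net$layer_sizes[l], net$layer_sizes[l + 1L], n_b)
  })
  prev_spikes <- lapply(seq_len(L), function(l) matrix(0, net$layer_sizes[l + 1L], n_b))
  spikes <- lapply(seq_len(L), function(l) array(0, c(net$layer_sizes[l + 1L], T_steps, n_b)))
  potentials <- spikes
  pre_traces <- lapply(seq_len(L), function(l) array(0, c(net$layer_sizes[l], T_steps, n_b)))

  for (t in seq_len(T_steps)) {
    pre_now <- matrix(x[, t, ], nrow = net$layer_sizes[1])
    for (l in seq_len(L)) {
      states[[l]] <- step_filters(states[[l]], pre_now, prev_spikes[[l]], net$filters)
      u <- membrane_potential(weights[[l]], states[[l]]$syn_traces,
                              if (net$refractory) states[[l]]$ref_traces else NULL)
      s <- if (relaxed) fire_relaxed(u, net$thresholds[l], slope) else fire(u, net$thresholds[l])
      pre_traces[[l]][, t, ] <- states[[l]]$syn_traces
      potentials[[l]][, t, ] <- u
      spikes[[l]][, t, ] <- s
      prev_spikes[[l]] <- s
      pre_now <- s  # becomes the next layer's current-step pre-synaptic input
    }
  }
  structure(list(spikes = spikes, potentials = potentials,
                 pre_traces = pre_traces, T = T_steps, n_batch = n_b),
            class = "srm_forward")
}

check_weight_shapes <- function(net, weights) {
  if (length(weights) != net$n_layers) {
    stop("need one weight matrix per trainable layer", call. = FALSE)
  }
  for (l in seq_len(net$n_layers)) {
    if (nrow(weights[[l]]) != net$layer_sizes[l + 1L] ||
        ncol(weights[[l]]) != net$layer_sizes[l]) {
      stop(sprintf("weights[[%d]] must be %d x %d", l,
                   net$layer_sizes[l + 1L], net$layer_sizes[l]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
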