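#' Predictive distribution containers
#'
#' A `predictive_distribution` stores, for each example, the per-class
#' predictive probabilities (rows of `probs`), the hard prediction (zero-based
#' argmax, ties broken toward the lowest class index) and its confidence
#' (the maximal probability).
#'
#' @param probs `N x C` matrix of probabilities (rows sum to 1).
#' @return A `predictive_distribution`.
#' @export
predictive_distribution <- function(probs) {
  probs <- as.matrix(probs)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("rows of `probs` must be probability vectors", call. = FALSE)
  }
  pred <- max.col(probs, ties.method = "first") - 1L
  conf <- probs[cbind(seq_len(nrow(probs)), pred + 1L)]
  structure(list(probs = probs, prediction = pred, confidence = conf),
            class = "predictive_distribution")
}

#' @export
print.predictive_distribution <- function(x, ...) {
  cat(sprintf("<predictive_distribution: %d examples, %d classes, mean confidence %.3f>\n",
              nrow(x$probs), ncol(x$probs), mean(x$confidence)))
  invisible(x)
}

# rate-averaged softmax read-out: probs over classes from the last layer's
# spike array (nY x T x B) -> B x C matrix
readout_probs <- function(spikes_L, B_L) {
  T_steps <- dim(spikes_L)[2]
  n_b <- dim(spikes_L)[3]
  probs <- matrix(0, n_b, nrow(B_L))
  for (t in seq_len(T_steps)) {
    probs <- probs + t(softmax(B_L %*% matrix(spikes_L[, t, ], nrow = dim(spikes_L)[1])))
  }
  probs / T_steps
}

#' Frequentist prediction from a single weight vector
#'
#' Runs one forward pass and averages, over time, the softmax of the read-out
#' layer's spikes projected through the final fixed read-out matrix:
#' `probs = (1/T) * sum_t Softmax(B_L s_t)`. A silent read-out layer yields
#' the uniform distribution.
#'
#' @param net A [layered_srm()].
#' @param weights Per-layer weight matrices (or an `snn_fit`'s `$weights`).
#' @param input Spike raster, batch array, or `spike_dataset`.
#' @return A [predictive_distribution()].
#' @export
predict_frequentist <- function(net, weights, input) {
  x <- if (inherits(input, "spike_dataset")) input$x else input
  fwd <- srm_forward(net, x, weights)
  predictive_distribution(readout_probs(fwd$spikes[[net$n_layers]],
                                        net$readout[[net$n_layers]]))
}

# draw one weight realization from either posterior family
posterior_draw <- function(posterior) {
  if (inherits(posterior, "gaussian_posterior")) {
    sample_weights(posterior)
  } else if (inherits(posterior, "bernoulli_posterior")) {
    hard_sample(posterior$logits)
  } else {
    stop("`posterior` must be a gaussian_posterior or bernoulli_posterior",
         call. = FALSE)
  }
}

#' Bayesian prediction by posterior averaging
#'
#' Averages the rate-softmax read-out over `n_s` weight realizations drawn
#' from the posterior. In `"committee"` mode the realizations are drawn once
#' and reused for every input (a committee machine); in `"ensemble"` mode each
#' input gets its own fresh draws. Both modes share the same sampling law, so
#' their expected predictive distributions coincide.
#'
#' @param net A [layered_srm()].
#' @param posterior A [gaussian_posterior()] or [bernoulli_posterior()].
#' @param input Spike raster, batch array, or `spike_dataset`.
#' @param n_s Number of posterior draws (default 10).
#' @param mode `"committee"` or `"ensemble"`.
#' @param seed Integer seed for the draws.
#' @return A [predictive_distribution()].
#' @export
predict_bayesian <- function(net, posterior, input, n_s = 10L,
                             mode = c("committee", "ensemble"), seed = 1L) {
  mode <- match.arg(mode)
  if (n_s < 1L) stop("`n_s` must be at least 1", call. = FALSE)
  x <- if (inherits(input, "spike_dataset")) input$x else input
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  n_b <- dim(x)[3]
  if (mode == "committee") {
    probs <- 0
    with_seed(seed, {
      for (s in seq_len(n_s)) {
        w <- posterior_draw(posterior)
        fwd <- srm_forward(net, x, w)
        probs <- probs + readout_probs(fwd$spikes[[net$n_layers]],
                                       net$readout[[net$n_layers]]) / n_s
      }
    })
    predictive_distribution(probs)
  } else {
    probs <- matrix(0, n_b, net$n_classes)
    for (i in seq_len(n_b)) {
      xi <- x[, , i, drop = FALSE]
      with_seed(seed + i, {
        for (s in seq_len(n_s)) {
          w <- posterior_draw(posterior)
          fwd <- srm_forward(net, xi, w)
          probs[i, ] <- probs[i, ] + readout_probs(fwd$spikes[[net$n_layers]],
                                                   net$readout[[net$n_layers]])[1, ] / n_s
        }
      })
    }
    predictive_distribution(probs)
  }
}

#' Hard decision and confidence
#'
#' Argmax class (ties toward the lowest index) and its probability for every
#' example of a predictive distribution.
#'
#' @param pd A [predictive_distribution()].
#' @return Tibble with `example`, `class` (zero-based) and `confidence`
#'   (always at least `1/C`).
#' @export
decide <- function(pd) {
  stopifnot(inherits(pd, "predictive_distribution"))
  tibble::tibble(example = seq_along(pd$prediction),
                 class = pd$prediction,
                 confidence = pd$confidence)
}
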