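# small shared fixtures; everything is generated in code under fixed seeds

tiny_net <- function(layer_sizes = c(4, 6, 3), n_classes = 2, seed = 3,
                     refractory = TRUE, threshold_mode = "unit") {
  layered_srm(layer_sizes, n_classes = n_classes, readout_seed = seed,
              refractory = refractory, threshold_mode = threshold_mode)
}

tiny_raster <- function(n = 4, T = 12, rate = 0.5, seed = 7) {
  set.seed(seed)
  spike_raster(matrix(stats::rbinom(n * T, 1, rate), n, T))
}

# two-class template dataset, linearly separable spike patterns
toy_dataset <- function(n_neurons = 20, T = 15, n_per_class = 12, seed = 5) {
  stream <- make_template_stream(n_classes = 2, classes_per_task = 2,
                                 n_neurons = n_neurons, T = T,
                                 template_density = 0.3, flip_prob = 0.05,
                                 n_train = n_per_class, n_test = n_per_class,
                                 seed = seed)
  stream$tasks[[1]]$train
}

# quadratic toy loss over +-1 (or relaxed) weight vectors: L(w) = ||Xw - y||^2/n
toy_binary_loss <- function(n_w, seed = 11) {
  set.seed(seed)
  X <- matrix(stats::rnorm(8 * n_w), 8, n_w)
  wstar <- sample(c(-1, 1), n_w, replace = TRUE)
  y <- as.vector(X %*% wstar) + stats::rnorm(8, sd = 0.3)
  list(
    loss = function(w) mean((X %*% w - y)^2),
    grad = function(w) as.vector(2 * t(X) %*% (X %*% w - y)) / length(y),
    w_star = wstar
  )
}
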