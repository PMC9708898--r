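#' Spike encoder configuration
#'
#' @param scheme `"population"` (Gaussian tuning curves, for low-dimensional
#'   continuous features) or `"rate"` (per-entry Bernoulli rates, for values
#'   already in \[0,1\]).
#' @param n_units_per_dim Neurons per input dimension (population scheme).
#' @param T Number of encoding time-steps.
#' @param tuning_width Gaussian tuning-curve width on the \[0,1\] feature
#'   scale; defaults to the center spacing `1/(n_units_per_dim - 1)`.
#' @param seed Integer seed used when drawing spikes.
#' @return An `encoder_config` object.
#' @export
encoder_config <- function(scheme = c("population", "rate"), n_units_per_dim = 10L,
                           T = 100L, tuning_width = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (T < 1L || n_units_per_dim < 1L) {
    stop("`T` and `n_units_per_dim` must be at least 1", call. = FALSE)
  }
  if (is.null(tuning_width)) {
    tuning_width <- if (n_units_per_dim > 1L) 1 / (n_units_per_dim - 1L) else 0.5
  }
  if (tuning_width <= 0) stop("`tuning_width` must be positive", call. = FALSE)
  structure(list(scheme = scheme, n_units_per_dim = as.integer(n_units_per_dim),
                 T = as.integer(T), tuning_width = tuning_width,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Min-max rescaling frozen on training data
#'
#' `fit_minmax()` records per-dimension minima and maxima of the training
#' features; `apply_minmax()` maps features affinely onto \[0,1\] with those
#' frozen statistics, so test and out-of-distribution inputs are rescaled
#' exactly as the training set was.
#'
#' @param x Numeric matrix (examples x dimensions).
#' @return `fit_minmax()`: a `minmax_scaler`; `apply_minmax()`: the rescaled
#'   matrix.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler A `minmax_scaler` from [fit_minmax()].
#' @export
apply_minmax <- function(x, scaler) {
  x <- as.matrix(x)
  rng <- pmax(scaler$max - scaler$min, .Machine$double.eps)
  sweep(sweep(x, 2, scaler$min), 2, rng, "/")
}

# Gaussian tuning-curve rates for one scaled input vector; rows are the
# n_units_per_dim * length(x) encoding neurons (dimension-major order).
population_rates <- function(x, cfg) {
  centers <- if (cfg$n_units_per_dim > 1L) {
    seq(0, 1, length.out = cfg$n_units_per_dim)
  } else 0.5
  as.vector(vapply(x, function(xi) {
    exp(-(xi - centers)^2 / (2 * cfg$tuning_width^2))
  }, numeric(cfg$n_units_per_dim)))
}

#' Population encoding of a feature vector
#'
#' Each input dimension is represented by `n_units_per_dim` neurons with
#' Gaussian tuning curves whose centers are evenly spaced on \[0,1\]. Neuron
#' `i` fires i.i.d. Bernoulli at each step with probability
#' `exp(-(x - c_i)^2 / (2 * tuning_width^2))`.
#'
#' Inputs are expected on the \[0,1\] scale (see [fit_minmax()]). Out-of-range
#' values are rejected by default; `oob = "clip"` saturates them to the covered
#' range (the natural behavior of bounded tuning curves, used when probing
#' points far outside the training distribution), and `oob = "allow"` evaluates
#' the tuning curves as-is.
#'
#' @param x Numeric feature vector scaled to \[0,1\] per dimension.
#' @param cfg An [encoder_config()] with `scheme = "population"`.
#' @param oob One of `"error"`, `"clip"`, `"allow"`.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return A [spike_raster()] of shape
#'   `(length(x) * n_units_per_dim) x T`.
#' @export
population_encode <- function(x, cfg, oob = c("error", "clip", "allow"), seed = NULL) {
  oob <- match.arg(oob)
  if (any(x < 0 | x > 1)) {
    if (oob == "error") {
      stop("population_encode: input outside [0,1] after rescaling", call. = FALSE)
    }
    if (oob == "clip") x <- pmin(pmax(x, 0), 1)
  }
  rates <- population_rates(x, cfg)
  with_seed(seed %||% cfg$seed, {
    spikes <- matrix(stats::rbinom(length(rates) * cfg$T, 1L, rep(rates, cfg$T)),
                     nrow = length(rates), ncol = cfg$T)
    spike_raster(spikes)
  })
}

#' Rate encoding of values in \[0,1\]
#'
#' Entry `v_k` spikes i.i.d. Bernoulli(`v_k`) at each of `T` steps.
#'
#' @param v Numeric vector with entries in \[0,1\].
#' @param T Number of time-steps.
#' @param seed Integer seed.
#' @return A [spike_raster()] of shape `length(v) x T`.
#' @export
rate_encode <- function(v, T, seed = 1L) {
  if (any(v < 0 | v > 1)) stop("rate_encode: values outside [0,1]", call. = FALSE)
  with_seed(seed, {
    spike_raster(matrix(stats::rbinom(length(v) * T, 1L, rep(v, T)),
                        nrow = length(v), ncol = T))
  })
}

#' One-hot target signal for a class label
#'
#' The target for a labeled example is the one-hot vector of its class
#' repeated at every time-step. Labels are zero-based (`0 <= label < C`),
#' matching the class indices used throughout the package.
#'
#' @param label Class index in `0:(C-1)`.
#' @param C Number of classes.
#' @param T Number of time-steps.
#' @return A `C x T` binary matrix whose columns all equal the one-hot vector.
#' @export
one_hot_targets <- function(label, C, T) {
  if (length(label) != 1L || label < 0 || label >= C || label != floor(label)) {
    stop("`label` must be a single integer in [0, C)", call. = FALSE)
  }
  targets <- matrix(0, C, T)
  targets[label + 1L, ] <- 1
  targets
}

# one-hot matrix (C x n) for a vector of zero-based labels
one_hot_matrix <- function(labels, C) {
  y <- matrix(0, C, length(labels))
  y[cbind(labels + 1L, seq_along(labels))] <- 1
  y
}

#' Encode a tabular dataset into a spike dataset
#'
#' Rescales features with a frozen [fit_minmax()] scaler (fitted here if not
#' supplied) and population- or rate-encodes every example into a spike
#' raster. The per-example spike draws are derived deterministically from
#' `cfg$seed`.
#'
#' @param points Numeric matrix or data frame (examples x dimensions).
#' @param labels Integer class labels, zero-based.
#' @param cfg An [encoder_config()].
#' @param scaler Optional pre-fitted `minmax_scaler` (use the training
#'   scaler when encoding test data).
#' @param oob Out-of-range policy passed to [population_encode()].
#' @return A `spike_dataset`: list with `x` (`n_in x T x N` array), `labels`,
#'   `n_classes`, `T`, and the `scaler` used.
#' @export
encode_dataset <- function(points, labels, cfg, scaler = NULL,
                           oob = c("error", "clip", "allow")) {
  oob <- match.arg(oob)
  points <- as.matrix(points)
  labels <- as.integer(labels)
  stopifnot(nrow(points) == length(labels))
  if (is.null(scaler)) scaler <- fit_minmax(points)
  scaled <- apply_minmax(points, scaler)
  n <- nrow(points)
  encode_one <- function(i) {
    if (cfg$scheme == "population") {
      population_encode(scaled[i, ], cfg, oob = oob, seed = cfg$seed + i)
    } else {
      v <- scaled[i, ]
      if (oob != "error") v <- pmin(pmax(v, 0), 1)
      rate_encode(v, cfg$T, seed = cfg$seed + i)
    }
  }
  first <- encode_one(1L)
  x <- array(0, c(nrow(first), cfg$T, n))
  x[, , 1L] <- first
  if (n > 1L) for (i in 2:n) x[, , i] <- encode_one(i)
  structure(list(x = x, labels = labels,
                 n_classes = length(unique(labels)) , T = cfg$T,
                 scaler = scaler),
            class = "spike_dataset")
}

#' Assemble a spike dataset from rasters and labels
#'
#' @param x `n_in x T x N` binary array (or list of rasters).
#' @param labels Zero-based integer labels, length N.
#' @param n_classes Number of classes (defaults to `max(labels) + 1`).
#' @return A `spike_dataset`.
#' @export
spike_dataset <- function(x, labels, n_classes = NULL) {
  if (is.list(x)) x <- simplify2array(x)
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  labels <- as.integer(labels)
  stopifnot(dim(x)[3] == length(labels))
  structure(list(x = x, labels = labels,
                 n_classes = as.integer(n_classes %||% (max(labels) + 1L)),
                 T = dim(x)[2]),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset: %d examples, %d input neurons x %d steps, %d classes>\n",
              dim(x$x)[3], dim(x$x)[1], x$T, x$n_classes))
  invisible(x)
}

# subset a spike_dataset by example index
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$x <- dataset$x[, , idx, drop = FALSE]
  out$labels <- dataset$labels[idx]
  out
}

# concatenate spike_datasets sharing geometry and class space
dataset_bind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(d) !is.null(d) && dim(d$x)[3] > 0, logical(1))]
  if (length(parts) == 1L) return(parts[[1L]])
  out <- parts[[1L]]
  out$x <- array(unlist(lapply(parts, function(d) as.vector(d$x))),
                 c(dim(parts[[1L]]$x)[1:2], sum(vapply(parts, function(d) dim(d$x)[3], 0))))
  out$labels <- unlist(lapply(parts, function(d) d$labels))
  out$n_classes <- max(vapply(parts, function(d) d$n_classes, 0L))
  out
}
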