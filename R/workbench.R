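#' Uniform symmetric weight quantization
#'
#' Post-hoc quantization to `2^n_bits` evenly spaced levels spanning
#' `[-range, range]` (both endpoints are levels). Values beyond the range are
#' clipped; rounding is half-to-even; the map is idempotent. Intended as an
#' evaluation-time emulation of limited-precision deployments, not as part of
#' the training loop.
#'
#' @param w Numeric weights (vector, matrix, or per-layer list).
#' @param n_bits Bits per weight (>= 2).
#' @param range Symmetric clip bound (> 0).
#' @return Quantized weights shaped like `w`.
#' @export
quantize_weights <- function(w, n_bits = 8L, range = 1) {
  if (n_bits < 2L) stop("`n_bits` must be at least 2", call. = FALSE)
  if (range <= 0) stop("`range` must be positive", call. = FALSE)
  step <- 2 * range / (2^n_bits - 1)
  smap(function(x) {
    x <- pmin(pmax(x, -range), range)
    -range + round((x + range) / step) * step
  }, w)
}

net_spec <- function(net) {
  list(layer_sizes = net$layer_sizes, n_classes = net$n_classes,
       thresholds = net$thresholds,
       tau_mem = net$filters$tau_mem, tau_syn = net$filters$tau_syn,
       tau_ref = net$filters$tau_ref,
       readout_seed = net$readout_seed, refractory = net$refractory)
}

net_from_spec <- function(spec) {
  layered_srm(spec$layer_sizes, spec$n_classes, thresholds = spec$thresholds,
              filters = filter_params(spec$tau_mem, spec$tau_syn, spec$tau_ref),
              readout_seed = spec$readout_seed, refractory = spec$refractory)
}

#' Save and load training checkpoints
#'
#' Checkpoints are JSON files containing the network specification (the fixed
#' read-out matrices are regenerated deterministically from their seed), the
#' trained parameters (weights, latent weights, or posterior parameters), and
#' the resolved training configuration with its seed — everything needed to
#' regenerate the run.
#'
#' @param fit An `snn_fit` or `svi_fit`.
#' @param path Output JSON file.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a list
#'   with `type`, `net`, and the stored parameters (`weights`, or `posterior`).
#' @export
save_checkpoint <- function(fit, path) {
  payload <- if (inherits(fit, "snn_fit")) {
    list(type = if (fit$binary) "ste" else "frequentist",
         net = net_spec(fit$net), cfg = unclass(fit$cfg),
         weights = fit$weights, latent = fit$latent)
  } else if (inherits(fit, "svi_fit")) {
    if (fit$family == "gaussian") {
      list(type = "gauss-vi", net = net_spec(fit$net), cfg = unclass(fit$cfg),
           m = fit$posterior$m, p = fit$posterior$p,
           prior_m0 = fit$prior$m0, prior_p0 = fit$prior$p0)
    } else {
      list(type = "bern-vi", net = net_spec(fit$net), cfg = unclass(fit$cfg),
           logits = fit$posterior$logits, prior_logits0 = fit$prior$logits0)
    }
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- net_from_spec(raw$net)
  as_mats <- function(x) lapply(x, function(m) as.matrix(m))
  out <- list(type = raw$type, net = net, cfg = raw$cfg)
  if (raw$type %in% c("frequentist", "ste")) {
    out$weights <- as_mats(raw$weights)
    if (!is.null(raw$latent)) out$latent <- as_mats(raw$latent)
  } else if (raw$type == "gauss-vi") {
    out$posterior <- gaussian_posterior(as_mats(raw$m), as_mats(raw$p))
  } else if (raw$type == "bern-vi") {
    out$posterior <- bernoulli_posterior(as_mats(raw$logits))
  }
  out
}

# build a spike dataset (and its companions) from a declarative spec list
build_dataset <- function(spec) {
  type <- spec$type %||% "two_moons"
  if (type == "two_moons") {
    pts <- make_two_moons(spec$n_per_class %||% 200L,
                          spec$noise_sigma %||% 0.1,
                          seed = spec$seed %||% 1L)
    cfg <- encoder_config("population",
                          n_units_per_dim = spec$n_units_per_dim %||% 10L,
                          T = spec$T %||% 100L,
                          seed = (spec$seed %||% 1L) + 1000L)
    dataset <- encode_dataset(cbind(pts$x1, pts$x2), pts$label, cfg)
    list(dataset = dataset, points = pts, encoder = cfg)
  } else if (type == "template_stream") {
    stream <- make_template_stream(
      n_classes = spec$n_classes %||% 4L,
      classes_per_task = spec$classes_per_task %||% 2L,
      n_neurons = spec$n_neurons %||% 30L, T = spec$T %||% 20L,
      template_density = spec$template_density %||% 0.3,
      flip_prob = spec$flip_prob %||% 0.05,
      n_train = spec$n_train %||% 40L, n_test = spec$n_test %||% 20L,
      template_mode = spec$template_mode %||% "random",
      seed = spec$seed %||% 1L)
    list(stream = stream)
  } else {
    stop(sprintf("unknown dataset type '%s'", type), call. = FALSE)
  }
}

resolve_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config$method <- config$method %||% "frequentist"
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% tempfile("run")
  config
}

#' Train a model from a declarative run configuration
#'
#' Dispatches on `method` (`"frequentist"`, `"ste"`, `"gauss-vi"`,
#' `"bern-vi"`), builds the dataset from `config$dataset`, the network from
#' `config$net`, trains, and writes three artifacts to `config$out_dir`:
#' `checkpoint.json`, `metrics.json` (per-epoch loss or free energy), and
#' `config.json` (the fully resolved configuration, seed included). Runs are
#' deterministic given the configuration.
#'
#' @param config Named list or path to a YAML file. Recognized top-level
#'   fields: `method`, `seed`, `out_dir`, `dataset` (see the dataset types in
#'   the package vignette), `net` (`hidden`, `threshold_mode`), and `train`
#'   (learning rate, batch size, epochs, and the VI parameters `rho`, `tau`,
#'   `n_mc` where applicable).
#' @return Invisibly, a list with the `fit`, the dataset bundle, and artifact
#'   paths.
#' @export
run_train <- function(config) {
  config <- resolve_run_config(config)
  if (!config$method %in% c("frequentist", "ste", "gauss-vi", "bern-vi")) {
    stop(sprintf("unknown method '%s'", config$method), call. = FALSE)
  }
  data <- build_dataset(c(config$dataset, list(seed = config$seed)))
  if (is.null(data$dataset)) {
    stop("run_train expects an offline dataset spec (e.g. two_moons)", call. = FALSE)
  }
  dataset <- data$dataset
  hidden <- config$net$hidden %||% 64L
  binaryish <- config$method %in% c("ste", "bern-vi")
  net <- layered_srm(
    c(dim(dataset$x)[1], hidden, config$net$readout %||% max(16L, dataset$n_classes)),
    n_classes = dataset$n_classes,
    threshold_mode = config$net$threshold_mode %||%
      (if (binaryish) "sqrt_fan_in" else "unit"),
    readout_seed = config$seed)
  tr <- config$train %||% list()
  fit <- switch(config$method,
    "frequentist" = train_frequentist(net, dataset,
      train_config(eta = tr$eta %||% 0.05, batch_size = tr$batch_size %||% 16L,
                   epochs = tr$epochs %||% 10L, seed = config$seed)),
    "ste" = train_frequentist(net, dataset,
      train_config(eta = tr$eta %||% 0.05, batch_size = tr$batch_size %||% 16L,
                   epochs = tr$epochs %||% 10L, seed = config$seed),
      binary = TRUE),
    "gauss-vi" = train_gaussian_vi(net, dataset,
      gaussian_prior(tr$m0 %||% 0, tr$p0 %||% 1),
      vi_config(rho = tr$rho %||% 0.1, eta = tr$eta %||% 0.05,
                batch_size = tr$batch_size %||% 16L,
                epochs = tr$epochs %||% 10L, seed = config$seed)),
    "bern-vi" = train_bernoulli_vi(net, dataset,
      bernoulli_prior(tr$prior_logits %||% 0),
      gs_config(tau = tr$tau %||% 1, eta = tr$eta %||% 0.05,
                rho = tr$rho %||% 0.1, batch_size = tr$batch_size %||% 16L,
                epochs = tr$epochs %||% 10L, seed = config$seed)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(config$out_dir, "checkpoint.json")
  save_checkpoint(fit, ckpt)
  trace <- if (inherits(fit, "svi_fit")) fit$fe_trace else fit$loss_trace
  utils::write.csv(trace, file.path(config$out_dir, "training_curve.csv"),
                   row.names = FALSE)
  metrics_path <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(list(method = config$method, seed = config$seed,
                            trace = trace),
                       metrics_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, data = data, checkpoint = ckpt,
                 metrics = metrics_path, out_dir = config$out_dir))
}

#' Run a continual-learning method over a task stream
#'
#' Builds a template task stream from `config$dataset`, trains the requested
#' continual method (`"sgd"`, `"ewc"`, `"bio"`, `"bayes-gauss"`,
#' `"bayes-bern"`), and writes the per-stage accuracy/ECE table to
#' `metrics.json` (plus `metrics.csv`) in `config$out_dir`.
#'
#' @param config Named list or YAML path: `method`, `seed`, `out_dir`,
#'   `dataset` (template-stream parameters), `net` (`hidden`), `train`
#'   (rates, epochs, `rho`, `tau`, `alpha`, `coreset_fraction`).
#' @return Invisibly, a list with the `continual_fit` and artifact paths.
#' @export
run_continual <- function(config) {
  config <- resolve_run_config(config)
  methods <- c("sgd", "ewc", "bio", "bayes-gauss", "bayes-bern")
  if (!config$method %in% methods) {
    stop(sprintf("unknown continual method '%s'", config$method), call. = FALSE)
  }
  spec <- c(config$dataset %||% list(), list(type = "template_stream",
                                             seed = config$seed))
  stream <- build_dataset(spec)$stream
  hidden <- config$net$hidden %||% 50L
  binaryish <- config$method == "bayes-bern"
  net <- layered_srm(c(dim(stream$tasks[[1]]$train$x)[1], hidden, 16L),
                     n_classes = stream$n_classes,
                     threshold_mode = if (binaryish) "sqrt_fan_in" else "unit",
                     readout_seed = config$seed)
  tr <- config$train %||% list()
  frac <- tr$coreset_fraction %||% 0.1
  fit <- switch(config$method,
    "sgd" = train_ewc(net, stream,
      train_config(eta = tr$eta %||% 0.05, batch_size = tr$batch_size %||% 10L,
                   epochs = tr$epochs %||% 15L, seed = config$seed),
      alpha = 0, coreset_fraction = 0),
    "ewc" = train_ewc(net, stream,
      train_config(eta = tr$eta %||% 0.05, batch_size = tr$batch_size %||% 10L,
                   epochs = tr$epochs %||% 15L, seed = config$seed),
      alpha = tr$alpha %||% 1, coreset_fraction = frac),
    "bio" = train_continual_bio(net, stream,
      train_config(eta = tr$eta %||% 0.05, batch_size = tr$batch_size %||% 10L,
                   epochs = tr$epochs %||% 15L, seed = config$seed)),
    "bayes-gauss" = train_continual_gaussian(net, stream,
      gaussian_prior(0, tr$p0 %||% 1),
      vi_config(rho = tr$rho %||% 0.01, eta = tr$eta %||% 0.2,
                batch_size = tr$batch_size %||% 10L,
                epochs = tr$epochs %||% 15L, seed = config$seed),
      coreset_fraction = frac),
    "bayes-bern" = train_continual_bernoulli(net, stream,
      bernoulli_prior(0),
      gs_config(tau = tr$tau %||% 1, eta = tr$eta %||% 0.05,
                rho = tr$rho %||% 0.05, batch_size = tr$batch_size %||% 10L,
                epochs = tr$epochs %||% 15L, seed = config$seed),
      coreset_fraction = frac))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics_json <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(list(method = config$method, seed = config$seed,
                            metrics = fit$metrics),
                       metrics_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(fit$metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, metrics = metrics_json, out_dir = config$out_dir))
}

#' Evaluate a checkpoint on a dataset
#'
#' Computes accuracy, the reliability report and ECE on the given dataset,
#' optionally writes the report JSON and plot files. Posterior checkpoints may
#' be evaluated in `"committee"` or `"ensemble"` mode; point-estimate
#' checkpoints only support `"map"` (single-pass) prediction and requesting a
#' sampling mode for them is an error.
#'
#' @param checkpoint Path to a checkpoint JSON or a loaded checkpoint list.
#' @param dataset A `spike_dataset` to evaluate on.
#' @param mode `"map"`, `"committee"`, or `"ensemble"`.
#' @param n_s Posterior draws for the sampling modes.
#' @param M Reliability bins.
#' @param seed Seed for posterior draws.
#' @param out_dir Optional directory for `calibration.json` and
#'   `reliability.png`.
#' @param n_bits,range Optional [quantize_weights()] settings applied to
#'   point-estimate weights before evaluation.
#' @return A `calibration_report` (with `accuracy`).
#' @export
run_evaluate <- function(checkpoint, dataset, mode = c("map", "committee", "ensemble"),
                         n_s = 10L, M = 10L, seed = 1L, out_dir = NULL,
                         n_bits = NULL, range = 1) {
  mode <- match.arg(mode)
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  is_bayes <- ck$type %in% c("gauss-vi", "bern-vi")
  if (!is_bayes && mode != "map") {
    stop("committee/ensemble prediction requires a posterior checkpoint",
         call. = FALSE)
  }
  pd <- if (mode == "map") {
    w <- if (is_bayes) {
      if (ck$type == "gauss-vi") ck$posterior$m else sign_ste(ck$posterior$logits)
    } else ck$weights
    if (!is.null(n_bits)) w <- quantize_weights(w, n_bits, range)
    predict_frequentist(ck$net, w, dataset)
  } else {
    predict_bayesian(ck$net, ck$posterior, dataset, n_s = n_s, mode = mode,
                     seed = seed)
  }
  report <- calibration_summary(pd, dataset$labels, M)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calibration_json(report, file.path(out_dir, "calibration.json"))
    ggplot2::ggsave(file.path(out_dir, "reliability.png"),
                    autoplot(report), width = 5, height = 4, dpi = 120)
  }
  report
}
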