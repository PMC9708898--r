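#' Two-moons uncertainty-quantification experiment
#'
#' Trains a frequentist and a Bayesian (Gaussian mean-field) SRM classifier on
#' the population-encoded two-moons task and compares them on a held-out set
#' (accuracy, ECE) and on the far-field portion of an evaluation grid
#' (mean predictive confidence). The Bayesian predictor is a committee of
#' `n_s` posterior draws. Out-of-range grid points are clipped to the
#' encoder's covered range before encoding.
#'
#' Default problem sizes (200 training points per class, noise 0.1, 10
#' encoding neurons per dimension over 50 steps, one hidden layer of 64, 15
#' epochs) keep the experiment at desk scale; they are documented in the
#' package vignette.
#'
#' @param seed Master seed; all data generation and training derive from it.
#' @param n_train,n_test Examples per class for training and held-out sets.
#' @param noise_sigma Two-moons noise standard deviation.
#' @param T Encoding steps.
#' @param hidden Hidden-layer size.
#' @param epochs Training epochs (both learners).
#' @param rho Free-energy temperature of the Bayesian learner.
#' @param eta_freq,eta_vi Learning rates.
#' @param n_s Committee size.
#' @param grid_bounds,grid_resolution Evaluation grid for the OOD probe.
#' @param far_dist Far-field distance threshold.
#' @return A list with `summary` (one-row tibble: accuracies, ECEs, mean OOD
#'   confidences, and their gap) and the underlying fits and reports.
#' @export
experiment_two_moons_uncertainty <- function(seed = 1L, n_train = 200L,
                                             n_test = 500L, noise_sigma = 0.1,
                                             T = 50L, hidden = 64L,
                                             epochs = 15L, rho = 0.01,
                                             eta_freq = 0.05, eta_vi = 0.2,
                                             n_s = 10L,
                                             grid_bounds = c(-4, 4),
                                             grid_resolution = 15L,
                                             far_dist = 3) {
  moons <- make_two_moons(n_train, noise_sigma, seed = seed + 10L)
  held <- make_two_moons(n_test, noise_sigma, seed = seed + 11L)
  enc <- encoder_config("population", n_units_per_dim = 10L, T = T,
                        seed = seed + 100L)
  train_ds <- encode_dataset(cbind(moons$x1, moons$x2), moons$label, enc)
  test_ds <- encode_dataset(cbind(held$x1, held$x2), held$label, enc,
                            scaler = train_ds$scaler, oob = "clip")
  grid <- make_ood_grid(grid_bounds, grid_resolution)
  ff <- far_field_points(grid, cbind(moons$x1, moons$x2), far_dist)
  ood_ds <- encode_dataset(cbind(ff$x1, ff$x2), rep(0L, nrow(ff)), enc,
                           scaler = train_ds$scaler, oob = "clip")

  net <- layered_srm(c(dim(train_ds$x)[1], hidden, 16L), n_classes = 2L,
                     readout_seed = seed + 5L)
  freq <- train_frequentist(net, train_ds,
                            train_config(eta = eta_freq, batch_size = 20L,
                                         epochs = epochs, seed = seed + 2L))
  bayes <- train_gaussian_vi(net, train_ds, gaussian_prior(0, 1),
                             vi_config(rho = rho, eta = eta_vi,
                                       batch_size = 20L, epochs = epochs,
                                       seed = seed + 2L))

  pf <- predict_frequentist(net, freq$weights, test_ds)
  pb <- predict_bayesian(net, bayes$posterior, test_ds, n_s = n_s,
                         mode = "committee", seed = seed + 3L)
  rep_f <- calibration_summary(pf, test_ds$labels)
  rep_b <- calibration_summary(pb, test_ds$labels)
  pfo <- predict_frequentist(net, freq$weights, ood_ds)
  pbo <- predict_bayesian(net, bayes$posterior, ood_ds, n_s = n_s,
                          mode = "committee", seed = seed + 3L)
  summary <- tibble::tibble(
    acc_frequentist = rep_f$accuracy, acc_bayesian = rep_b$accuracy,
    ece_frequentist = rep_f$ece, ece_bayesian = rep_b$ece,
    ood_conf_frequentist = mean(pfo$confidence),
    ood_conf_bayesian = mean(pbo$confidence),
    ood_conf_gap = mean(pfo$confidence) - mean(pbo$confidence),
    n_far_field = nrow(ff))
  list(summary = summary, report_frequentist = rep_f, report_bayesian = rep_b,
       ood_frequentist = pfo, ood_bayesian = pbo,
       fit_frequentist = freq, fit_bayesian = bayes, net = net)
}

#' Two-task continual-learning contrast experiment
#'
#' Builds a two-task stream of orthogonal spike templates (4 classes in pairs)
#' and trains three learners task-sequentially: plain SGD (no replay, no
#' regularization), frequentist EWC with a 7.5% coreset, and Bayesian
#' Gaussian continual learning with a 10% coreset and posterior-as-prior
#' chaining. The quantity of interest is task-1 test accuracy after training
#' on task 2 (retention); plain SGD exhibits catastrophic forgetting while
#' the Bayesian learner retains the first task.
#'
#' @param seeds Integer vector; the experiment repeats once per seed and the
#'   summary averages over repeats.
#' @param n_neurons,T Template geometry.
#' @param hidden Hidden-layer size.
#' @param n_train,n_test Examples per class.
#' @param epochs Epochs per task.
#' @param rho,eta_vi Bayesian learner parameters.
#' @param eta_freq SGD/EWC learning rate.
#' @param ewc_alpha EWC regularization strength.
#' @return A list with `summary` (per-method mean retention and final
#'   accuracies) and `runs` (per-seed tibble).
#' @export
experiment_continual_contrast <- function(seeds = 1:3, n_neurons = 32L,
                                          T = 20L, hidden = 50L,
                                          n_train = 40L, n_test = 20L,
                                          epochs = 15L, rho = 0.01,
                                          eta_vi = 0.2, eta_freq = 0.05,
                                          ewc_alpha = 1) {
  runs <- purrr::map_dfr(seeds, function(seed) {
    stream <- make_template_stream(n_classes = 4L, classes_per_task = 2L,
                                   n_neurons = n_neurons, T = T,
                                   template_density = 0.3, flip_prob = 0.05,
                                   n_train = n_train, n_test = n_test,
                                   template_mode = "orthogonal", seed = seed)
    net <- layered_srm(c(n_neurons, hidden, 16L), n_classes = 4L,
                       readout_seed = seed)
    fits <- list(
      sgd = train_ewc(net, stream,
                      train_config(eta = eta_freq, batch_size = 10L,
                                   epochs = epochs, seed = seed),
                      alpha = 0, coreset_fraction = 0),
      ewc = train_ewc(net, stream,
                      train_config(eta = eta_freq, batch_size = 10L,
                                   epochs = epochs, seed = seed),
                      alpha = ewc_alpha, coreset_fraction = 0.075),
      bayes_gauss = train_continual_gaussian(net, stream, gaussian_prior(0, 1),
                                             vi_config(rho = rho, eta = eta_vi,
                                                       batch_size = 10L,
                                                       epochs = epochs,
                                                       seed = seed),
                                             coreset_fraction = 0.1))
    purrr::map_dfr(names(fits), function(nm) {
      m <- fits[[nm]]$metrics
      tibble::tibble(
        seed = seed, method = nm,
        task1_after_task1 = m$accuracy[m$stage == 1 & m$task == 1],
        task1_after_task2 = m$accuracy[m$stage == 2 & m$task == 1],
        task2_after_task2 = m$accuracy[m$stage == 2 & m$task == 2],
        ece_mean_final = mean(m$ece[m$stage == 2]))
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$method),
    task1_after_task1 = mean(.data$task1_after_task1),
    task1_retention = mean(.data$task1_after_task2),
    task2_final = mean(.data$task2_after_task2),
    .groups = "drop")
  list(summary = summary, runs = runs)
}
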