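make_stream <- function(seed = 3, n_train = 10, n_test = 6, n_neurons = 24, T = 12) {
  make_template_stream(n_classes = 4, classes_per_task = 2,
                       n_neurons = n_neurons, T = T, template_density = 0.3,
                       flip_prob = 0.05, n_train = n_train, n_test = n_test,
                       template_mode = "orthogonal", seed = seed)
}

test_that("coreset selection is class-balanced with round-half-up sizes", {
  labels <- rep(0:1, each = 400)
  ds <- spike_dataset(array(0, c(1, 1, 800)), labels)
  idx <- select_coreset(ds, 0.075, seed = 1)
  expect_equal(as.vector(table(labels[idx])), c(30L, 30L))  # 7.5% of 400
  expect_equal(select_coreset(ds, 0, seed = 1), integer(0))
  expect_identical(select_coreset(ds, 0.2, seed = 5), select_coreset(ds, 0.2, seed = 5))
  # round half up: 10% of 25 -> 2.5 -> 3
  ds25 <- spike_dataset(array(0, c(1, 1, 25)), rep(0L, 25))
  expect_length(select_coreset(ds25, 0.1, seed = 2), 3L)
  expect_error(select_coreset(ds, 1.5), "0, 1")
})

# dataset_subset is internal; reconstruct the same subset via the constructor
dataset_subset_public <- function(ds, idx) {
  spike_dataset(ds$x[, , idx, drop = FALSE], ds$labels[idx],
                n_classes = ds$n_classes)
}

test_that("the Fisher diagonal is nonnegative, zero for silent input, additive", {
  net <- tiny_net(c(24, 8, 4), n_classes = 4)
  w <- init_weights(net, seed = 2)
  st <- make_stream()
  ds <- st$tasks[[1]]$train
  f_all <- fim_diag(net, w, ds)
  expect_true(all(unlist(f_all) >= 0))
  # silent input -> zero traces -> zero gradients -> zero FIM
  silent <- spike_dataset(array(0, c(24, 12, 3)), c(0L, 1L, 0L), n_classes = 4)
  expect_true(all(unlist(fim_diag(net, w, silent)) == 0))
  # additive over a split of the dataset
  n <- length(ds$labels)
  half <- seq_len(n %/% 2)
  f1 <- fim_diag(net, w, dataset_subset_public(ds, half))
  f2 <- fim_diag(net, w, dataset_subset_public(ds, setdiff(seq_len(n), half)))
  for (l in seq_along(f_all)) {
    expect_equal(f_all[[l]], f1[[l]] + f2[[l]], tolerance = 1e-10)
  }
})

test_that("the EWC penalty matches its quadratic form", {
  st <- ewc_state(alpha = 1)
  w <- list(matrix(c(1, 2), 1))
  st$anchors[[1]] <- list(matrix(c(0, 0), 1))
  st$fims[[1]] <- list(matrix(c(3, 1), 1))
  expect_equal(ewc_penalty(w, st), 3 * 1 + 1 * 4)  # (1,2) with F = diag(3,1)
  expect_equal(ewc_penalty(st$anchors[[1]], st), 0)
  st$fims[[1]] <- list(matrix(c(1, 1), 1))
  expect_equal(ewc_penalty(w, st), 1 + 4)  # identity FIM -> squared distance
})

test_that("a one-task stream reduces EWC training to offline training", {
  st <- make_template_stream(n_classes = 2, classes_per_task = 2,
                             n_neurons = 20, T = 10, n_train = 8, n_test = 4,
                             seed = 6)
  net <- tiny_net(c(20, 8, 4))
  cfg <- train_config(eta = 0.05, batch_size = 4, epochs = 3, seed = 2)
  cont <- train_ewc(net, st, cfg, alpha = 0, coreset_fraction = 0)
  off <- train_frequentist(net, st$tasks[[1]]$train, cfg)
  expect_equal(cont$weights, off$weights, tolerance = 1e-12)
})

test_that("accuracy matrices have one row block per stage with entries in [0,1]", {
  st <- make_stream()
  net <- tiny_net(c(24, 10, 6), n_classes = 4)
  fit <- train_ewc(net, st, train_config(eta = 0.05, batch_size = 5,
                                         epochs = 2, seed = 1),
                   alpha = 1, coreset_fraction = 0.1)
  expect_equal(sort(unique(fit$metrics$stage)), c(1L, 2L))
  expect_equal(sort(unique(fit$metrics$task)), c(1L, 2L))
  expect_true(all(fit$metrics$accuracy >= 0 & fit$metrics$accuracy <= 1))
  expect_true(all(fit$metrics$ece >= 0 & fit$metrics$ece <= 1))
  expect_length(fit$ewc$anchors, 2L)
  expect_length(fit$coresets[[1]], 2L)  # 10% of 10 per class, two classes
})

test_that("bio plasticity state updates follow their rules", {
  w <- list(matrix(c(1, -1, 2, 0), 2))
  st <- bio_plasticity_state(w, delta_nu = 0.5, kappa = 1, gamma = 0.1,
                             rate_threshold = 0.2)
  # rates below threshold leave nu unchanged
  st1 <- bio_state_update(st, list(c(0.1, 0.1)), list(c(0.1, 0.1)), w)
  expect_true(all(st1$nu[[1]] == 0))
  # kappa = 1 makes the reference weight jump to the current weight
  expect_equal(st1$w_ref[[1]], w[[1]])
  # both rates above threshold bump nu by delta_nu
  st2 <- bio_state_update(st, list(c(0.5, 0.5)), list(c(0.5, 0.5)), w)
  expect_true(all(st2$nu[[1]] == 0.5))
  # kappa = 0.5 moves halfway: w_ref 0 -> 1 when w = 2
  st3 <- bio_plasticity_state(list(matrix(2)), kappa = 0.5)
  st3 <- bio_state_update(st3, list(1), list(1), list(matrix(2)))
  expect_equal(st3$w_ref[[1]][1, 1], 1)
})

test_that("the bio weight update is metaplasticity-damped and spike-gated", {
  w <- matrix(1)
  # nu = 0: full plasticity, update scales by exp(0) = 1
  w1 <- bio_weight_update(w, nu = matrix(0), w_ref = matrix(0), e_it = 1,
                          s_j_t = 1, s_i_t = 0, u_it = 1, threshold = 1,
                          eta = 0.1, gamma = 0.1)
  expect_equal(w1[1, 1], 1 - 0.1 * 0.25)
  # no pre or post spikes: both terms gated off
  w2 <- bio_weight_update(w, matrix(2), matrix(0), 1, 0, 0, 1, 1, 0.1, 0.1)
  expect_equal(w2[1, 1], 1)
  # nu * w = 2: the update is scaled by exp(-2)
  w3 <- bio_weight_update(w, matrix(2), matrix(0), 1, 1, 0, 1, 1, 0.1, 0)
  expect_equal(1 - w3[1, 1], exp(-2) * 0.1 * 0.25, tolerance = 1e-12)
})

test_that("bio continual training runs end to end", {
  st <- make_stream(n_train = 6, n_test = 4)
  net <- tiny_net(c(24, 8, 6), n_classes = 4)
  fit <- train_continual_bio(net, st, train_config(eta = 0.05, batch_size = 3,
                                                   epochs = 1, seed = 2))
  expect_s3_class(fit, "continual_fit")
  expect_true(all(is.finite(unlist(fit$weights))))
  expect_true(all(unlist(fit$bio$nu) >= 0))
})

test_that("Gaussian prior chaining hands the posterior to the next task bit-identically", {
  st <- make_stream(n_train = 6, n_test = 4)
  net <- tiny_net(c(24, 8, 6), n_classes = 4)
  fit <- train_continual_gaussian(net, st, gaussian_prior(0, 1),
                                  vi_config(rho = 0.05, eta = 0.1,
                                            batch_size = 3, epochs = 1, seed = 2),
                                  coreset_fraction = 0.2, n_s = 3)
  expect_identical(fit$priors[[2]]$m0, fit$posteriors[[1]]$m)
  expect_identical(fit$priors[[2]]$p0, fit$posteriors[[1]]$p)
  expect_equal(nrow(fit$precision_trace), 2L)
})

test_that("a one-task stream reduces Bayesian continual to offline VI", {
  st <- make_template_stream(n_classes = 2, classes_per_task = 2,
                             n_neurons = 20, T = 10, n_train = 6, n_test = 4,
                             seed = 6)
  net <- tiny_net(c(20, 8, 4))
  cfg <- vi_config(rho = 0.05, eta = 0.1, batch_size = 3, epochs = 2, seed = 5)
  cont <- train_continual_gaussian(net, st, gaussian_prior(0, 1), cfg,
                                   coreset_fraction = 0.1, n_s = 2)
  off <- train_gaussian_vi(net, st$tasks[[1]]$train, gaussian_prior(0, 1), cfg)
  expect_equal(cont$posteriors[[1]]$m, off$posterior$m, tolerance = 1e-12)
  expect_equal(cont$posteriors[[1]]$p, off$posterior$p, tolerance = 1e-12)
})

test_that("Bernoulli continual training chains logits and stays finite", {
  st <- make_stream(n_train = 6, n_test = 4)
  net <- tiny_net(c(24, 8, 6), n_classes = 4, threshold_mode = "sqrt_fan_in")
  fit <- train_continual_bernoulli(net, st, bernoulli_prior(0),
                                   gs_config(tau = 1, eta = 0.05, rho = 0.05,
                                             batch_size = 3, epochs = 1, seed = 2),
                                   coreset_fraction = 0.2, n_s = 3)
  expect_true(all(is.finite(unlist(fit$posterior$logits))))
  expect_length(fit$posteriors, 2L)
  expect_true(all(fit$metrics$accuracy >= 0 & fit$metrics$accuracy <= 1))
})
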