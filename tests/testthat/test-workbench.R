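test_that("quantization is idempotent, clipped, and half-to-even", {
  w <- matrix(c(-2, -0.5, 0, 0.3, 0.5, 2), 2)
  q <- quantize_weights(w, n_bits = 8, range = 1)
  expect_identical(quantize_weights(q, n_bits = 8, range = 1), q)
  expect_true(all(abs(q) <= 1))
  expect_equal(q[1, 1], -1)   # clipped
  expect_equal(q[2, 3], 1)    # clipped
  # w = 0.5 maps to the nearest of the 256 levels spanning [-1, 1]
  step <- 2 / 255
  expect_equal(q[1, 3], -1 + round((0.5 + 1) / step) * step, tolerance = 1e-12)
  expect_lte(abs(q[1, 3] - 0.5), step / 2)
  # a value exactly between two levels rounds to the even level index:
  # with 2 bits over [-1.5, 1.5] the levels are -1.5, -0.5, 0.5, 1.5 and
  # w = 0 (exactly between -0.5 and 0.5) rounds to the even index, 0.5
  expect_equal(quantize_weights(0, n_bits = 2, range = 1.5), 0.5)
  expect_error(quantize_weights(w, n_bits = 1), "at least 2")
  # per-layer lists pass through smap
  ql <- quantize_weights(list(w, w * 2), 4, 1)
  expect_length(ql, 2L)
})

test_that("checkpoints round-trip weights and posteriors through JSON", {
  ds <- toy_dataset(n_per_class = 4, T = 8)
  net <- tiny_net(c(20, 6, 4))
  fit <- train_frequentist(net, ds, train_config(epochs = 1, batch_size = 4, seed = 2))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(back$type, "frequentist")
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(back$net$layer_sizes, net$layer_sizes)
  expect_equal(back$net$readout, net$readout, tolerance = 1e-12)

  vfit <- train_gaussian_vi(net, ds, gaussian_prior(0, 1),
                            vi_config(rho = 0.05, eta = 0.1, batch_size = 4,
                                      epochs = 1, seed = 3))
  path2 <- tempfile(fileext = ".json")
  save_checkpoint(vfit, path2)
  back2 <- load_checkpoint(path2)
  expect_s3_class(back2$posterior, "gaussian_posterior")
  expect_equal(back2$posterior$m, vfit$posterior$m, tolerance = 1e-12)
  expect_equal(back2$posterior$p, vfit$posterior$p, tolerance = 1e-12)
})

test_that("run_train produces reproducible artifacts for each method", {
  cfgl <- list(method = "frequentist", seed = 4,
               dataset = list(type = "two_moons", n_per_class = 10,
                              n_units_per_dim = 4, T = 10),
               net = list(hidden = 8, readout = 6),
               train = list(epochs = 2, batch_size = 5),
               out_dir = tempfile("runA"))
  r1 <- run_train(cfgl)
  expect_true(file.exists(r1$checkpoint))
  expect_true(file.exists(r1$metrics))
  expect_true(file.exists(file.path(r1$out_dir, "config.json")))
  cfgl$out_dir <- tempfile("runB")
  r2 <- run_train(cfgl)
  m1 <- jsonlite::read_json(r1$metrics, simplifyVector = TRUE)
  m2 <- jsonlite::read_json(r2$metrics, simplifyVector = TRUE)
  expect_identical(m1$trace, m2$trace)

  cfgl$method <- "gauss-vi"
  cfgl$train$rho <- 0.05
  cfgl$out_dir <- tempfile("runC")
  r3 <- run_train(cfgl)
  ck <- load_checkpoint(r3$checkpoint)
  expect_equal(ck$type, "gauss-vi")
})

test_that("run_train rejects unknown methods and stream-only datasets", {
  expect_error(run_train(list(method = "nope",
                              dataset = list(type = "two_moons"))), "unknown")
  expect_error(run_train(list(method = "frequentist",
                              dataset = list(type = "template_stream"))),
               "offline dataset")
  expect_error(spikebayes:::build_dataset(list(type = "mystery")),
               "unknown dataset")
})

test_that("run_evaluate enforces checkpoint/mode compatibility", {
  ds <- toy_dataset(n_per_class = 4, T = 8)
  net <- tiny_net(c(20, 6, 4))
  fit <- train_frequentist(net, ds, train_config(epochs = 1, batch_size = 4, seed = 2))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  expect_error(run_evaluate(path, ds, mode = "committee"), "posterior")
  rep <- run_evaluate(path, ds, mode = "map", out_dir = tempfile("eval"))
  expect_s3_class(rep, "calibration_report")
  expect_true(!is.null(rep$accuracy))
  # quantized evaluation stays in range
  rep8 <- run_evaluate(path, ds, mode = "map", n_bits = 8, range = 1)
  expect_s3_class(rep8, "calibration_report")
})

test_that("run_continual dispatches methods over a template stream", {
  cfgl <- list(method = "bayes-gauss", seed = 3,
               dataset = list(n_classes = 4, classes_per_task = 2,
                              n_neurons = 16, T = 8, n_train = 6, n_test = 4),
               net = list(hidden = 8),
               train = list(epochs = 1, batch_size = 3, rho = 0.05, eta = 0.1),
               out_dir = tempfile("cont"))
  r <- run_continual(cfgl)
  expect_s3_class(r$fit, "continual_fit")
  expect_true(file.exists(r$metrics))
  expect_true(file.exists(file.path(r$out_dir, "metrics.csv")))
  expect_error(run_continual(list(method = "bogus")), "unknown continual")
})

test_that("YAML configurations drive run_train", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(method = "frequentist", seed = 2,
                        dataset = list(type = "two_moons", n_per_class = 8,
                                       n_units_per_dim = 4, T = 8),
                        net = list(hidden = 6, readout = 4),
                        train = list(epochs = 1, batch_size = 4),
                        out_dir = tempfile("runY")), path)
  r <- run_train(path)
  expect_s3_class(r$fit, "snn_fit")
})

test_that("tidy and glance methods return tibbles of the right shape", {
  ds <- toy_dataset(n_per_class = 4, T = 8)
  net <- tiny_net(c(20, 6, 4))
  fit <- train_frequentist(net, ds, train_config(epochs = 2, batch_size = 4, seed = 2))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 2L)
  g <- glance(fit)
  expect_equal(g$epochs, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
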