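test_that("hard decisions use the lowest-index tie-break", {
  pd <- predictive_distribution(rbind(c(0.2, 0.5, 0.3),
                                      c(1, 1, 1) / 3,
                                      c(0.25, 0.25, 0.5)))
  d <- decide(pd)
  expect_equal(d$class, c(1L, 0L, 2L))
  expect_equal(d$confidence[1], 0.5)
  expect_true(all(d$confidence >= 1 / 3))
  expect_error(predictive_distribution(rbind(c(0.5, 0.2))), "probability")
})

test_that("reliability bins reproduce the hand-worked example exactly", {
  d <- data.frame(confidence = c(0.6, 0.6, 0.9, 0.9),
                  correct = c(TRUE, TRUE, TRUE, FALSE))
  r <- reliability_bins(d, 10)
  b6 <- r$bins[r$bins$bin == 6, ]
  b9 <- r$bins[r$bins$bin == 9, ]
  expect_equal(b6$count, 2L); expect_equal(b6$acc, 1.0); expect_equal(b6$conf, 0.6)
  expect_equal(b9$count, 2L); expect_equal(b9$acc, 0.5); expect_equal(b9$conf, 0.9)
  expect_equal(r$ece, 0.4)
  expect_equal(sum(r$bins$count), 4L)
})

test_that("bin boundaries are half-open on the left", {
  # confidence exactly m/M lands in bin m
  d <- data.frame(confidence = c(0.1, 0.2, 1.0), correct = c(TRUE, TRUE, TRUE))
  r <- reliability_bins(d, 10)
  expect_equal(r$bins$count[c(1, 2, 10)], c(1L, 1L, 1L))
  expect_error(reliability_bins(data.frame(confidence = 0, correct = TRUE), 10),
               "0, 1")
})

test_that("perfectly calibrated bins give zero ECE and ECE is bounded", {
  d <- data.frame(confidence = rep(1, 10), correct = rep(TRUE, 10))
  expect_equal(reliability_bins(d, 10)$ece, 0)
  set.seed(2)
  d2 <- data.frame(confidence = runif(500, 0.01, 1), correct = runif(500) < 0.5)
  expect_lte(reliability_bins(d2, 10)$ece, 1)
})

test_that("synthetic perfectly calibrated decisions give near-zero ECE", {
  set.seed(6)
  n <- 1e5
  conf <- runif(n, 0.5, 1)
  correct <- runif(n) < conf
  r <- reliability_bins(data.frame(confidence = conf, correct = correct), 10)
  expect_lte(r$ece, 0.01)
})

test_that("the OOD histogram counts over the reliability bins", {
  h <- ood_histogram(c(0.95, 0.91, 0.99), 10)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$count[10], 3L)
  h2 <- ood_histogram(runif(50, 0.01, 1), 5)
  expect_equal(sum(h2$count), 50L)
})

test_that("silent networks predict the uniform distribution", {
  net <- tiny_net(c(4, 5, 3), n_classes = 3)
  w0 <- lapply(init_weights(net, 1), function(m) m * 0)
  pd <- predict_frequentist(net, w0, tiny_raster())
  expect_equal(pd$probs[1, ], rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pd$prediction, 0L)  # uniform ties break to class 0
  expect_equal(rowSums(pd$probs), 1, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a single committee draw reduces to frequentist prediction", {
  net <- tiny_net(c(6, 5, 3), n_classes = 2)
  post <- gaussian_posterior(init_weights(net, seed = 3),
                             lapply(init_weights(net, 1), function(m) m * 0 + 4))
  x <- tiny_raster(6, 10)
  pb <- predict_bayesian(net, post, x, n_s = 1, mode = "committee", seed = 11)
  w <- spikebayes::sample_weights(post, seed = 11)
  pf <- predict_frequentist(net, w, x)
  expect_equal(pb$probs, pf$probs, tolerance = 1e-12)
})

test_that("committee and ensemble agree in expectation on a concentrated posterior", {
  net <- tiny_net(c(6, 5, 3), n_classes = 2)
  m <- init_weights(net, seed = 3)
  post <- gaussian_posterior(m, lapply(m, function(x) x * 0 + 1e10))
  x <- tiny_raster(6, 10)
  pc <- predict_bayesian(net, post, x, n_s = 3, mode = "committee", seed = 1)
  pe <- predict_bayesian(net, post, x, n_s = 3, mode = "ensemble", seed = 2)
  pf <- predict_frequentist(net, m, x)
  expect_equal(pc$probs, pf$probs, tolerance = 1e-4)
  expect_equal(pe$probs, pf$probs, tolerance = 1e-4)
})

test_that("scoring and summary wire predictions into the report", {
  pd <- predictive_distribution(rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.7, 0.3)))
  rep <- calibration_summary(pd, c(0, 1, 1), M = 10)
  expect_equal(rep$accuracy, 2 / 3, tolerance = 1e-12)
  expect_s3_class(rep, "calibration_report")
  expect_equal(rep$n, 3L)
})

test_that("calibration reports serialize to JSON and plot", {
  d <- data.frame(confidence = c(0.6, 0.8), correct = c(TRUE, FALSE))
  r <- reliability_bins(d, 5)
  path <- tempfile(fileext = ".json")
  write_calibration_json(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$M, 5)
  expect_equal(back$ece, r$ece, tolerance = 1e-12)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
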