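test_that("probability/logit conversion is exact and guarded", {
  expect_equal(prob_to_logit(0.5), 0)
  expect_equal(prob_to_logit(0.9), 0.5 * log(9), tolerance = 1e-12)
  p <- c(0.01, 0.3, 0.73, 0.999)
  expect_equal(sigmoid(2 * prob_to_logit(p)), p, tolerance = 1e-12)
  expect_error(prob_to_logit(0), "strictly")
  expect_error(prob_to_logit(1), "strictly")
})

test_that("posterior keeps logits, probabilities and means consistent", {
  post <- bernoulli_posterior(c(-1.2, 0, 0.7))
  expect_equal(post$mu, tanh(post$logits), tolerance = 1e-12)
  expect_equal(post$prob, (post$mu + 1) / 2, tolerance = 1e-12)
})

test_that("Gumbel-softmax samples stay in (-1,1) and match the tanh identity", {
  cfg <- gs_config(tau = 0.7, eta = 0.1, rho = 0.1)
  w <- gumbel_sample(rep(0.3, 10000), cfg, seed = 4)
  expect_true(all(w > -1 & w < 1))
  # epsilon = 0.5 gives delta = 0, so the median sample is tanh(logit / tau);
  # tanh is monotone, so the sample median estimates exactly that value
  expect_lt(abs(stats::median(w) - tanh(0.3 / 0.7)), 0.02)
})

test_that("the low-temperature marginal is Bernoulli(sigma(2 logit))", {
  cfg <- gs_config(tau = 0.01, eta = 0.1, rho = 0.1)
  wr <- 0.5
  w <- gumbel_sample(rep(wr, 1e5), cfg, seed = 8)
  p_hat <- mean(w > 0)
  p_true <- sigmoid(2 * wr)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("hard samples are exactly +-1 with the documented sign convention", {
  w <- hard_sample(rep(0, 1000), seed = 2)
  expect_true(all(w %in% c(-1, 1)))
  # strongly positive logits give +1 almost surely
  expect_true(all(hard_sample(rep(20, 100), seed = 3) == 1))
})

test_that("gradient estimate multiplier reduces to identity at tau=1, logits 0, w=0", {
  cfg <- gs_config(tau = 1, eta = 0.1, rho = 0.1)
  expect_equal(grad_estimate(3.5, 0, 0, cfg), 3.5)
  expect_equal(grad_estimate(0, 0.4, 0.2, cfg), 0)
})

test_that("enumerated mean-parameter gradient matches numerical differentiation", {
  toy <- toy_binary_loss(3)
  logits <- c(0.4, -0.3, 0.1)
  g <- bernoulli_mu_grad_enum(toy$loss, logits)
  # numerical derivative of the enumerated expectation w.r.t. mu
  mu <- tanh(logits)
  e_of_mu <- function(mu) {
    configs <- enum_configs(3)
    probs <- apply((1 + t(t(configs) * mu)) / 2, 1, prod)
    sum(probs * apply(configs, 1, toy$loss))
  }
  h <- 1e-6
  fd <- vapply(1:3, function(i) {
    up <- mu; dn <- mu; up[i] <- up[i] + h; dn[i] <- dn[i] - h
    (e_of_mu(up) - e_of_mu(dn)) / (2 * h)
  }, 0)
  expect_equal(g, fd, tolerance = 1e-6)
})

test_that("the Gumbel-softmax estimator is approximately unbiased at small tau", {
  toy <- toy_binary_loss(3)
  logits <- c(0.4, -0.3, 0.1)
  exact <- bernoulli_mu_grad_enum(toy$loss, logits)
  cfg <- gs_config(tau = 0.05, eta = 0.1, rho = 0.1)
  set.seed(99)
  n <- 2e4
  est <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    w <- gumbel_sample(logits, cfg)
    est[i, ] <- grad_estimate(toy$grad(w), w, logits, cfg)
  }
  se <- apply(est, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(est) - exact) <= 3 * se))
})

test_that("logit update matches its rule and fixed points", {
  prior <- bernoulli_prior(0)
  cfg <- gs_config(tau = 1, eta = 0.1, rho = 0.5)
  # worked value: 0.95 * 1 - 0.1 * 2 = 0.75
  expect_equal(update_logits(1, 2, prior, cfg), 0.75)
  expect_equal(update_logits(0, 0, prior, cfg), 0)
  cfg0 <- gs_config(tau = 1, eta = 1e-12, rho = 0.5)
  expect_equal(update_logits(1.3, 5, prior, cfg0), 1.3, tolerance = 1e-9)
  expect_error(gs_config(tau = 1, eta = 0.5, rho = 3), "below 1")
  expect_error(gs_config(tau = 0), "positive")
})

test_that("the enumerated Gibbs posterior lower-bounds factorized free energies", {
  toy <- toy_binary_loss(4)
  rho <- 0.5
  f_gibbs <- gibbs_free_energy(toy$loss, 4, 0, rho)
  set.seed(3)
  for (rep in 1:20) {
    logits <- rnorm(4)
    expect_lte(f_gibbs,
               bernoulli_free_energy_enum(toy$loss, logits, 0, rho) + 1e-10)
  }
})

test_that("Bernoulli VI training is reproducible and keeps logits finite", {
  ds <- toy_dataset(n_per_class = 5, T = 8)
  net <- tiny_net(c(20, 6, 4), threshold_mode = "sqrt_fan_in")
  cfg <- gs_config(tau = 1, eta = 0.05, rho = 0.05, batch_size = 5,
                   epochs = 2, seed = 4)
  f1 <- train_bernoulli_vi(net, ds, bernoulli_prior(0), cfg)
  f2 <- train_bernoulli_vi(net, ds, bernoulli_prior(0), cfg)
  expect_identical(f1$posterior$logits, f2$posterior$logits)
  expect_true(all(is.finite(unlist(f1$posterior$logits))))
})
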