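test_that("config guards the convex-combination regime", {
  expect_error(vi_config(rho = 2, eta = 0.6), "below 1")
  expect_error(vi_config(eta = 0), "positive")
  expect_error(vi_config(n_mc = 0), "at least 1")
  expect_s3_class(vi_config(rho = 1, eta = 0.5), "vi_config")
})

test_that("posterior samples follow N(m, 1/p)", {
  post <- gaussian_posterior(m = 3, p = 1e12)
  expect_lt(abs(sample_weights(post, seed = 1) - 3), 1e-5)
  post <- gaussian_posterior(m = 0, p = 1)
  set.seed(5)
  draws <- vapply(1:1e5, function(i) sample_weights(post), 0)
  expect_lt(abs(mean(draws)), 3 / sqrt(1e5))
  expect_lt(abs(var(draws) - 1), 3 * sqrt(2 / 1e5))
  expect_identical(sample_weights(post, seed = 42), sample_weights(post, seed = 42))
})

test_that("precision update matches its rule and fixed points", {
  prior <- gaussian_prior(m0 = 0, p0 = 1)
  cfg <- vi_config(rho = 0.5, eta = 0.1)
  # worked value: 0.95 * 1 + 0.1 * (4 + 0.5) = 1.4
  post <- gaussian_posterior(m = 0, p = 1)
  expect_equal(update_precision(post, 4, prior, cfg)$p, 1.4)
  # zero gradients at p = p0 is a fixed point
  expect_equal(update_precision(gaussian_posterior(0, 1), 0, prior, cfg)$p, 1)
  # eta = 0 leaves everything unchanged
  cfg0 <- vi_config(rho = 0.5, eta = 1e-12)
  expect_equal(update_precision(gaussian_posterior(0, 2), 7, prior, cfg0)$p, 2,
               tolerance = 1e-9)
})

test_that("mean update matches its rule and fixed points", {
  prior <- gaussian_prior(m0 = 0, p0 = 1)
  cfg <- vi_config(rho = 0.5, eta = 0.1)
  # worked value: 1 - 0.1/2 * (0 - 0.5*(0 - 1)) = 0.975
  post <- gaussian_posterior(m = 1, p = 2)
  expect_equal(update_mean(post, 0, prior, cfg)$m, 0.975)
  # zero gradient at m = m0 is a fixed point
  post2 <- gaussian_posterior(m = 0, p = 2)
  expect_equal(update_mean(post2, 0, prior, cfg)$m, 0)
})

test_that("precision stays positive under random update sequences", {
  set.seed(77)
  prior <- gaussian_prior(0, 0.5)
  cfg <- vi_config(rho = 0.9, eta = 1, p_floor = 1e-6)
  post <- gaussian_posterior(rnorm(20), rexp(20), p_floor = 1e-6)
  for (i in 1:200) {
    post <- update_precision(post, rexp(20, rate = 5), prior, cfg)
    post <- update_mean(post, rnorm(20), prior, cfg)
    expect_true(all(post$p >= 1e-6))
  }
})

test_that("closed-form Gaussian KL agrees with a Monte-Carlo estimate", {
  set.seed(12)
  for (rep in 1:3) {
    post <- gaussian_posterior(rnorm(1), rexp(1) + 0.2)
    prior <- gaussian_prior(rnorm(1), rexp(1) + 0.2)
    n <- 2e5
    w <- post$m + rnorm(n) / sqrt(post$p)
    logq <- dnorm(w, post$m, 1 / sqrt(post$p), log = TRUE)
    logp <- dnorm(w, prior$m0, 1 / sqrt(prior$p0), log = TRUE)
    diff <- logq - logp
    expect_lt(abs(gaussian_kl(post, prior) - mean(diff)), 3 * sd(diff) / sqrt(n))
  }
})

test_that("at rho = 0 the recorded free energy is the expected loss alone", {
  ds <- toy_dataset(n_per_class = 5, T = 8)
  net <- tiny_net(c(20, 6, 4))
  fit <- train_gaussian_vi(net, ds, gaussian_prior(0, 1),
                           vi_config(rho = 0, eta = 0.1, batch_size = 5,
                                     epochs = 2, seed = 3))
  # KL term weighted by rho = 0: free energy equals the sampled dataset loss,
  # which is nonnegative and finite
  expect_true(all(is.finite(fit$fe_trace$free_energy)))
  expect_true(all(fit$fe_trace$free_energy >= 0))
  kl <- gaussian_kl(fit$posterior, fit$prior)
  expect_gt(kl, 0)  # posterior moved, yet contributes nothing at rho = 0
})

test_that("Gaussian VI training is reproducible under a fixed seed", {
  ds <- toy_dataset(n_per_class = 5, T = 8)
  net <- tiny_net(c(20, 6, 4))
  cfg <- vi_config(rho = 0.05, eta = 0.1, batch_size = 5, epochs = 2, seed = 9)
  f1 <- train_gaussian_vi(net, ds, gaussian_prior(0, 1), cfg)
  f2 <- train_gaussian_vi(net, ds, gaussian_prior(0, 1), cfg)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$fe_trace, f2$fe_trace)
})

test_that("multi-sample updates run and keep the posterior finite", {
  ds <- toy_dataset(n_per_class = 4, T = 6)
  net <- tiny_net(c(20, 5, 3))
  fit <- train_gaussian_vi(net, ds, gaussian_prior(0, 1),
                           vi_config(rho = 0.05, eta = 0.1, n_mc = 2,
                                     batch_size = 4, epochs = 1, seed = 2))
  expect_true(all(is.finite(unlist(fit$posterior$m))))
  expect_true(all(unlist(fit$posterior$p) > 0))
})
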