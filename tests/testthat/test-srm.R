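test_that("filter parameters are validated at construction", {
  expect_error(filter_params(tau_mem = 0), "positive")
  expect_error(filter_params(tau_syn = -1), "positive")
  expect_error(filter_params(tau_mem = 5, tau_syn = 5), "differ")
  expect_s3_class(filter_params(20, 5, 10), "filter_params")
})

test_that("filter recursion reproduces the closed-form impulse responses", {
  fp <- filter_params(20, 5, 10)
  st <- new_srm_state(1, 1)
  syn <- numeric(50)
  ref <- numeric(50)
  for (t in 1:50) {
    # pre spike fed at step 1; post spike emitted at step 1 (seen from step 2)
    st <- step_filters(st, matrix(as.numeric(t == 1), 1, 1),
                       matrix(as.numeric(t == 2), 1, 1), fp)
    syn[t] <- st$syn_traces[1, 1]
    ref[t] <- st$ref_traces[1, 1]
  }
  # k steps after the spike the synaptic trace equals alpha_k (alpha_0 = 0)
  expect_lt(max(abs(syn - alpha_kernel(0:49, fp))), 1e-10)
  # refractory trace decays geometrically from exp(-1/tau_ref)
  expect_lt(max(abs(ref[2:50] - beta_kernel(1:49, fp))), 1e-10)
  expect_equal(ref[3] / ref[2], exp(-1 / fp$tau_ref), tolerance = 1e-12)
})

test_that("all-zero spike history leaves every trace at zero", {
  fp <- filter_params()
  st <- new_srm_state(3, 2, n_batch = 2)
  for (t in 1:10) {
    st <- step_filters(st, matrix(0, 3, 2), matrix(0, 2, 2), fp)
  }
  expect_true(all(st$syn_traces == 0))
  expect_true(all(st$ref_traces == 0))
})

test_that("membrane potential is the weighted trace sum minus feedback", {
  expect_equal(membrane_potential(matrix(2, 1, 1), 0.5)[1, 1], 1.0)
  expect_equal(membrane_potential(matrix(0, 2, 3), c(1, 2, 3)), matrix(0, 2, 1))
  expect_equal(membrane_potential(matrix(1, 1, 1), 1, ref_traces = matrix(0.4, 1, 1))[1, 1],
               0.6)
  expect_error(membrane_potential(matrix(1, 2, 2), c(1, 2, 3)), "match")
})

test_that("forward potentials equal the brute-force convolution", {
  # one trainable layer; compare simulated potentials against the explicit
  # double sum over the spike history with the closed-form kernels
  net <- layered_srm(c(3, 2), n_classes = 2, readout_seed = 1)
  set.seed(10)
  w <- init_weights(net, seed = 4, scale = 3)
  x <- matrix(rbinom(3 * 20, 1, 0.5), 3, 20)
  fwd <- srm_forward(net, x, w)
  fp <- net$filters
  for (t in 1:20) {
    for (i in 1:2) {
      syn <- sum(vapply(1:3, function(j) {
        w[[1]][i, j] * sum(alpha_kernel(seq_len(t - 1), fp) *
                             rev(x[j, seq_len(t - 1)]))
      }, 0))
      ref <- if (t > 1) {
        sum(beta_kernel(seq_len(t - 1), fp) * rev(fwd$spikes[[1]][i, seq_len(t - 1), 1]))
      } else 0
      expect_equal(fwd$potentials[[1]][i, t, 1], syn - ref, tolerance = 1e-10)
    }
  }
})

test_that("fire uses the inclusive threshold convention", {
  expect_equal(fire(0.5, 1), 0)
  expect_equal(fire(1.2, 1), 1)
  expect_equal(fire(1, 1), 1)  # Theta(0) = 1
  expect_equal(fire(c(-1, 0, 2), 0), c(0, 1, 1))
})

test_that("forward pass is deterministic, binary, and silent at zero weights", {
  net <- tiny_net()
  w <- init_weights(net, seed = 2)
  x <- tiny_raster()
  f1 <- srm_forward(net, x, w)
  f2 <- srm_forward(net, x, w)
  expect_identical(f1, f2)
  expect_true(all(unlist(lapply(f1$spikes, function(s) s %in% c(0, 1)))))
  w0 <- lapply(w, function(m) m * 0)
  f0 <- srm_forward(net, x, w0)
  expect_true(all(unlist(f0$spikes) == 0))
})

test_that("potentials are additive in the weights without refractory feedback", {
  net <- tiny_net(refractory = FALSE)
  wa <- init_weights(net, seed = 1)
  wb <- init_weights(net, seed = 2)
  wab <- Map(`+`, wa, wb)
  x <- tiny_raster()
  ua <- srm_forward(net, x, wa)$potentials[[1]]
  ub <- srm_forward(net, x, wb)$potentials[[1]]
  uab <- srm_forward(net, x, wab)$potentials[[1]]
  expect_equal(uab, ua + ub, tolerance = 1e-12)
})

test_that("binary weights with sqrt fan-in thresholds give fractional rates", {
  net <- layered_srm(c(30, 20, 10), n_classes = 2,
                     threshold_mode = "sqrt_fan_in", readout_seed = 8)
  expect_equal(net$thresholds, sqrt(c(30, 20)))
  w <- init_weights(net, seed = 9, binary = TRUE)
  set.seed(21)
  x <- matrix(rbinom(30 * 40, 1, 0.5), 30, 40)
  fwd <- srm_forward(net, x, w)
  rates <- rowMeans(fwd$spikes[[1]][, , 1])
  expect_true(any(rates > 0 & rates < 1))
})

test_that("weight shape mismatches are rejected", {
  net <- tiny_net()
  w <- init_weights(net, seed = 1)
  w[[1]] <- w[[1]][, -1]
  expect_error(srm_forward(net, tiny_raster(), w), "must be")
  expect_error(srm_forward(net, tiny_raster(n = 3), init_weights(net, 1)),
               "input")
})
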