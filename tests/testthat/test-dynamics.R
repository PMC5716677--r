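settle_to_ss <- function(stepper, n = 2000) {
  V <- 0
  for (i in seq_len(n)) V <- stepper(V)
  V
}

test_that("somatic voltages converge to the attenuated dendritic drive", {
  p <- neuron_params()                      # g_b = 0.6, g_l = 0.1, g_a = 0
  expect_equal(settle_to_ss(function(V) step_hidden_soma(V, 2, 0, p)),
               1.714286, tolerance = 1e-6)
  p2 <- neuron_params(g_a = 0.6)
  expect_equal(settle_to_ss(function(V) step_hidden_soma(V, 2, 2, p2)),
               2 * 1.2 / 1.3, tolerance = 1e-6)
  expect_equal(settle_to_ss(function(V) step_output_soma(V, 1, 0, p)),
               attenuation_factors(p)$k_d, tolerance = 1e-6)
  # rest is a fixed point
  expect_identical(step_hidden_soma(0, 0, 0, p), 0)
})

test_that("the teaching current saturates the target unit and silences the rest", {
  p <- neuron_params()
  V <- c(0, 0)
  for (i in 1:2000) {
    I <- teaching_current(V, target_class = 1, phase = "target", params = p)
    V <- step_output_soma(V, c(0, 0), I, p)
  }
  expect_equal(V[1], 4.70588, tolerance = 1e-5)
  expect_gt(firing_rates(V[1], p$phi_max), 0.99 * p$phi_max)
  expect_lt(firing_rates(V[2], p$phi_max), 0.01 * p$phi_max)
  # forward phase: no current at all
  expect_identical(teaching_current(c(1, 2), 1, "forward", p), c(0, 0))
  expect_error(teaching_current(c(0, 0), 5, "target", p), "out of range")
})

test_that("the rate function is the scaled logistic", {
  expect_equal(firing_rates(0, 0.2), 0.1)                 # 100 Hz at rest
  expect_equal(firing_rates(2, 0.2) * 1000, 176.159, tolerance = 1e-3)
  expect_equal(firing_rates(50, 0.2), 0.2, tolerance = 1e-9)
})

test_that("Poisson spike sampling matches the requested rate", {
  set.seed(5)
  n <- 1e5
  sp <- replicate(20, mean(sample_spikes(rep(0.2, n / 20), dt = 1)))
  expect_lt(abs(mean(sp) - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_false(any(sample_spikes(numeric(100))))
  expect_error(sample_spikes(-0.1), "negative")
  set.seed(42); a <- sample_spikes(rep(0.1, 50))
  set.seed(42); b <- sample_spikes(rep(0.1, 50))
  expect_identical(a, b)
})

test_that("dendritic voltages are exact affine maps", {
  expect_equal(dendrite_voltage(matrix(c(1, 2), 1), c(0.1, 0.2), 0.5), 1.0)
  expect_equal(dendrite_voltage(matrix(0, 3, 2), c(1, 1)), rep(0, 3))
  expect_error(dendrite_voltage(matrix(1, 2, 2), c(1, 1, 1)), "mismatch")
})

test_that("initial weights keep dendritic voltages in [-6, 12]", {
  set.seed(9)
  init <- init_weights(50, 784, phi_max = 0.2)
  expect_true(all(init$W >= -6 / (784 * 0.2)))
  expect_true(all(init$W <= 12 / (784 * 0.2)))
  expect_equal(range(init$W), c(-0.0382653, 0.0765306), tolerance = 1e-2)
  expect_identical(init$b, numeric(50))
  vb <- dendrite_voltage(init$W, rep(0.2, 784), init$b)
  expect_true(all(vb >= -6 & vb <= 12))
  set.seed(7); w1 <- init_weights(3, 4)$W
  set.seed(7); w2 <- init_weights(3, 4)$W
  expect_identical(w1, w2)
})

test_that("with g_a = 0 the apical compartment cannot influence the soma", {
  set.seed(21)
  net <- dendrite_network(6, hidden = 5, n_classes = 3,
                          params = neuron_params(g_a = 0))
  net2 <- net
  net2$Y[[1]]$Y <- net$Y[[1]]$Y * 7      # very different feedback weights
  rates <- rep(0.1, 6)
  set.seed(33)
  t1 <- run_trial(net, rates, target_class = 1, steps_forward = 60,
                  steps_target = 60)
  set.seed(33)
  t2 <- run_trial(net2, rates, target_class = 1, steps_forward = 60,
                  steps_target = 60)
  expect_identical(t1$forward$v, t2$forward$v)
  expect_identical(t1$target$phi, t2$target$phi)
  # while the apical voltages themselves do differ
  expect_false(isTRUE(all.equal(t1$forward$va, t2$forward$va)))
})
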