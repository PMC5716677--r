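test_that("attenuation factors follow the conductance ratios", {
  p <- neuron_params()
  att <- attenuation_factors(p)
  expect_equal(att$k_d, 0.857143, tolerance = 1e-6)
  expect_equal(att$k_b, 0.857143, tolerance = 1e-6)
  expect_equal(attenuation_factors(neuron_params(g_a = 0.6))$k_b,
               0.461538, tolerance = 1e-5)
  expect_equal(error_scaling(0.2), list(P0 = 100, P1 = 500))
})

test_that("targets and losses follow their definitions", {
  set.seed(30)
  net <- dendrite_network(4, hidden = 3, n_classes = 2)
  x <- c(0.1, 0.05, 0.2, 0.15)
  # consistent trial with matching plateaus: both losses vanish against a
  # target equal to the forward activity
  trial0 <- make_consistent_trial(net, x, trial_phi <- NULL)
  trial0$target$phi$output <- trial0$forward$phi$output
  expect_identical(output_target(trial0), trial0$forward$phi$output)
  l <- losses(trial0, net)
  expect_equal(l$output, 0)
  expect_equal(l$hidden, 0)
  # hidden target arithmetic and a one-unit output difference of 0.1
  trial1 <- make_consistent_trial(net, x, phi1_star = NULL,
                                  dalpha = list(c(0.1, 0, 0)))
  trial1$forward$phi$hidden1 <- rep(0.05, 3)
  expect_equal(hidden_target(trial1, 1), c(0.15, 0.05, 0.05))
  trial1$target$phi$output <- trial0$forward$phi$output + c(0.1, 0)
  expect_equal(losses(trial1, net)$output, 0.01)
  # test-mode trials carry no target phase
  expect_error(output_target(list(target = NULL)), "target phase")
})

test_that("output gradients match central differences of the half-squared loss", {
  set.seed(31)
  net <- dendrite_network(3, hidden = NULL, n_classes = 2)
  p <- net$params
  k_d <- attenuation_factors(p)$k_d
  x <- c(0.12, 0.03, 0.18)
  phi_star <- c(0.19, 0.01)
  trial <- make_consistent_trial(net, x, phi1_star = phi_star)
  g <- output_gradients(trial, net)
  loss_w <- function(W) {
    0.5 * sum((phi_star - p$phi_max *
                 sig(k_d * drop(W %*% x + net$b[[1]])))^2)
  }
  expect_lt(rel_err(g$dW, fd_grad(loss_w, net$W[[1]])), 1e-6)
  loss_b <- function(b) {
    0.5 * sum((phi_star - p$phi_max *
                 sig(k_d * drop(net$W[[1]] %*% x + b)))^2)
  }
  expect_lt(rel_err(g$db, fd_grad(loss_b, net$b[[1]])), 1e-6)
  # zero error -> zero gradient; sign: positive error raises the row
  trial0 <- make_consistent_trial(net, x, trial_phi <- NULL)
  trial0$target$phi$output <- trial0$forward$phi$output
  g0 <- output_gradients(trial0, net)
  expect_equal(g0$dW, matrix(0, 2, 3))
  # positive error on a unit makes -eta * dW raise that unit's row
  trial_p <- trial0
  trial_p$target$phi$output <- trial0$forward$phi$output + 0.05
  gp <- output_gradients(trial_p, net)
  expect_true(all(gp$dW < 0))
})

test_that("hidden gradients match central differences and are local", {
  set.seed(32)
  net <- dendrite_network(4, hidden = 3, n_classes = 2)
  p <- net$params
  k_b <- attenuation_factors(p)$k_b
  x <- c(0.05, 0.11, 0.02, 0.17)
  dalpha <- list(c(0.07, -0.04, 0.02))
  trial <- make_consistent_trial(net, x, phi1_star = NULL, dalpha = dalpha)
  g <- hidden_gradients(trial, net, 1)
  # target held fixed at the current consistent state plus the plateau step
  phi0_star <- p$phi_max * sig(k_b * drop(net$W[[1]] %*% x + net$b[[1]])) +
    dalpha[[1]]
  loss_w <- function(W) {
    0.5 * sum((phi0_star - p$phi_max * sig(k_b * drop(W %*% x +
                                                        net$b[[1]])))^2)
  }
  expect_lt(rel_err(g$dW, fd_grad(loss_w, net$W[[1]])), 1e-6)
  # equal plateaus -> zero update; silent input -> zero weight, nonzero bias
  trial0 <- make_consistent_trial(net, x, NULL, dalpha = list(rep(0, 3)))
  expect_equal(hidden_gradients(trial0, net, 1)$dW, matrix(0, 3, 4))
  trial_s <- make_consistent_trial(net, rep(0, 4), NULL, dalpha = dalpha)
  gs <- hidden_gradients(trial_s, net, 1)
  expect_equal(gs$dW, matrix(0, 3, 4))
  expect_false(all(gs$db == 0))
  # locality: output-layer state cannot influence the hidden update
  trial2 <- trial
  trial2$forward$v$output <- trial$forward$v$output + 3
  trial2$forward$s$output <- trial$forward$s$output * 2
  trial2$target$phi$output <- trial$target$phi$output + 0.05
  expect_identical(hidden_gradients(trial2, net, 1), g)
})

test_that("the backprop oracle is the exact gradient of the composed rate model", {
  set.seed(33)
  net <- dendrite_network(4, hidden = 3, n_classes = 2)
  p <- net$params
  att <- attenuation_factors(p)
  x <- c(0.15, 0.02, 0.09, 0.2)
  phi_star <- c(0.18, 0.02)
  trial <- make_consistent_trial(net, x, phi1_star = phi_star)
  composed <- function(W0) {
    h <- p$phi_max * sig(att$k_b * drop(W0 %*% x + net$b[[1]]))
    yhat <- p$phi_max * sig(att$k_d * drop(net$W[[2]] %*% h + net$b[[2]]))
    0.5 * sum((phi_star - yhat)^2)
  }
  for (style in c("spikes", "rates")) {
    bp <- backprop_oracle_update(net, trial, feedback_style = style)
    expect_lt(rel_err(bp$dW, fd_grad(composed, net$W[[1]])), 1e-6)
  }
  # zero output error -> zero oracle update
  trial0 <- make_consistent_trial(net, x, NULL)
  trial0$target$phi$output <- trial0$forward$phi$output
  expect_equal(backprop_oracle_update(net, trial0)$dW, matrix(0, 3, 4))
  net2 <- dendrite_network(4, hidden = c(3, 3), n_classes = 2)
  expect_error(backprop_oracle_update(net2, trial), "one-hidden-layer")
})

test_that("updates are scaled by eta and the P factors and refresh symmetric feedback", {
  set.seed(34)
  net <- dendrite_network(4, hidden = 3, n_classes = 2,
                          feedback = "symmetric")
  expect_equal(net$Y[[1]]$Y, t(net$W[[2]]))
  zero <- lapply(net$W, function(W) list(dW = W * 0, db = numeric(nrow(W))))
  expect_identical(apply_updates(net, zero, c(0.21, 0.21))$W, net$W)
  g <- lapply(net$W, function(W) list(dW = W * 0 + 0.01,
                                      db = rep(0.01, nrow(W))))
  expect_identical(apply_updates(net, g, 0)$W, net$W)
  upd <- apply_updates(net, g, c(0.21, 0.21))
  expect_equal(upd$W[[1]], net$W[[1]] - 0.21 * 100 * 0.01)   # P0 = 20/phi_max
  expect_equal(upd$W[[2]], net$W[[2]] - 0.21 * 500 * 0.01)   # P1 = 20/phi_max^2
  expect_equal(upd$Y[[1]]$Y, t(upd$W[[2]]))
  g[[1]]$dW[1, 1] <- NaN
  expect_error(apply_updates(net, g, 0.2), "non-finite")
})

test_that("depth-specific default learning rates are used", {
  expect_identical(default_learning_rates(0), 0.19)
  expect_identical(default_learning_rates(1), c(0.21, 0.21))
  expect_identical(default_learning_rates(2), c(0.23, 0.23, 0.12))
})

test_that("feedback constructors implement the four modes", {
  set.seed(35)
  W1 <- matrix(rnorm(10 * 20), 10, 20)
  sp <- make_feedback(W1, "sparse", phi_max = 0.2)
  expect_identical(sum(sp$Y == 0), as.integer(ceiling(0.8 * length(sp$Y))))
  nz <- sp$Y[sp$Y != 0] / 5
  expect_true(all(nz >= -6 / (10 * 0.2) & nz <= 12 / (10 * 0.2)))
  sym <- make_feedback(W1, "symmetric")
  expect_identical(sym$Y, t(W1))
  syn <- make_feedback(W1, "symmetric_noise", noise_sd = 0.05)
  expect_equal(syn$Y, t(W1) + syn$noise)
  expect_lt(abs(sd(syn$noise) - 0.05), 0.01)
  rnd <- make_feedback(W1, "random", phi_max = 0.2)
  expect_true(all(rnd$Y >= -3 & rnd$Y <= 6))
})
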