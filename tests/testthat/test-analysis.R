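test_that("update angles behave like angles", {
  a <- matrix(rnorm(12), 3, 4)
  expect_equal(update_angle(a, 2 * a), 0)
  expect_equal(update_angle(c(1, 0), c(0, 1)), 90)
  set.seed(41)
  u <- rnorm(392000); v <- rnorm(392000)
  expect_lt(abs(update_angle(u, v) - 90), 0.3)
  expect_error(update_angle(a, a * 0), "zero-norm")
  expect_error(update_angle(a, a[1:2, ]), "mismatch")
})

test_that("sliding means are trailing-window averages", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(sliding_mean(x, 2), c(1, 1.5, 2.5, 3.5, 4.5))
  expect_equal(sliding_mean(x, 10), cumsum(x) / seq_along(x))
})

test_that("receptive-field similarity separates real from shuffled fields", {
  set.seed(42)
  grid <- seq(0, 2 * pi, length.out = 60)
  smooth_fields <- t(sapply(1:8, function(i)
    sin(i * grid / 2) + 0.1 * rnorm(60)))
  rf <- receptive_field_similarity(smooth_fields, smooth_fields)
  expect_true(all(rf$r_max > 0.999))
  expect_gt(mean(rf$r_max), mean(rf$r_shuffled) + 0.3)
  const <- rbind(rep(1, 60))
  expect_true(is.na(receptive_field_similarity(const, smooth_fields)$r_max))
  expect_error(receptive_field_similarity(smooth_fields,
                                          smooth_fields[, 1:10]),
               "dimensionality")
})

test_that("loss correlation detects coordinated losses and its control does not", {
  set.seed(43)
  L0 <- runif(200)
  rec <- tibble::tibble(label = rep(0:1, each = 100),
                        loss_hidden1 = L0, loss_output = L0)
  lc <- loss_correlation(rec)
  expect_equal(lc$r, c(1, 1))
  expect_true(all(abs(lc$r_shuffled) < 0.3))
  # degenerate variance is reported as missing
  rec2 <- tibble::tibble(label = 0, loss_hidden1 = rep(1, 5),
                         loss_output = 1:5)
  expect_true(is.na(loss_correlation(rec2)$r))
})

test_that("the eigenvalue monitor matches direct linear algebra", {
  set.seed(44)
  # explicit small case: function output vs an independent SVD route
  Jb <- matrix(rnorm(12), 4, 3)
  Jg <- matrix(rnorm(12), 3, 4)
  mu <- dendritenet:::jacobian_mu(Jb, Jg)
  expect_equal(mu, max(svd(diag(4) - Jb %*% Jg)$d)^2, tolerance = 1e-10)
  # an exact right-inverse cancels the identity
  Jb2 <- matrix(rnorm(15), 3, 5)
  Jg2 <- MASS::ginv(Jb2)
  expect_equal(dendritenet:::jacobian_mu(Jb2, Jg2), 0, tolerance = 1e-10)
  # zero feedback leaves the identity: mu = 1
  W1 <- matrix(rnorm(3 * 6), 3, 6)
  expect_equal(jacobian_product_eigenvalue(W1, matrix(0, 6, 3),
                                           runif(6, 0, 0.2),
                                           runif(3, 0, 0.2)),
               1, tolerance = 1e-12)
})

test_that("the settling bound reproduces the analytic formula", {
  # independent arrangement of the same algebra
  tl <- 7.3; ts <- 2.1; r <- 0.05
  expect_equal(lemma1_bound(tl, ts, r),
               (2 * (tl * ts * r)^2) / ((tl - ts)^2 * (tl + ts)))
  expect_equal(signif(lemma1_bound(10, 3, 0.02), 3), 0.00113)
})

test_that("filtered traces estimate the firing rate (stationary regime)", {
  set.seed(45)
  mc <- lemma1_mc_check(rate = 0.02, window = 500, reps = 300)
  expect_lt(mc$rel_error, 0.05)
  expect_equal(lemma1_mc_check(rate = 0, window = 100,
                               reps = 10)$mean_trace, 0)
  # cold start carries the edge deficit ~ (tau_l + tau_s)/window
  set.seed(46)
  cold <- lemma1_mc_check(rate = 0.02, window = 500, reps = 500,
                          burn_in = 0)
  expect_lt(cold$mean_trace, 0.02)
  expect_equal(cold$rel_error, 13 / 500, tolerance = 0.35)
})
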