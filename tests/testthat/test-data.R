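test_that("the synthetic generator honours its contract", {
  set.seed(51)
  d <- synthetic_dataset(5, 32, 100, noise_sd = 0.08)
  expect_s3_class(d, "dendrite_dataset")
  expect_equal(dim(d$images), c(500, 32))
  expect_identical(sort(unique(d$labels)), 0:4)
  expect_true(all(d$images >= 0 & d$images <= 1))
  set.seed(51)
  d2 <- synthetic_dataset(5, 32, 100, noise_sd = 0.08)
  expect_identical(d, d2)
  # zero noise reproduces the prototypes exactly
  set.seed(52)
  d0 <- synthetic_dataset(3, 16, 4, noise_sd = 0)
  expect_equal(d0$images, d0$prototypes[d0$labels + 1L, ])
  expect_s3_class(tibble::as_tibble(d), "tbl_df")
})

test_that("class means recover the prototypes away from the clipping boundary", {
  set.seed(53)
  n <- 400
  d <- synthetic_dataset(4, 48, n, noise_sd = 0.08)
  for (k in 0:3) {
    proto <- d$prototypes[k + 1, ]
    interior <- proto > 0.15 & proto < 0.85   # clipping-free pixels
    cm <- colMeans(d$images[d$labels == k, ])
    expect_lt(max(abs(cm[interior] - proto[interior])),
              3 * 0.08 / sqrt(n) + 0.005)
  }
})

test_that("inseparable noise levels are rejected at generation", {
  set.seed(54)
  expect_error(synthetic_dataset(10, 16, 30, noise_sd = 1.5),
               "lower noise_sd")
  set.seed(54)
  expect_s3_class(synthetic_dataset(10, 16, 30, noise_sd = 1.5,
                                    check_separability = FALSE),
                  "dendrite_dataset")
})

test_that("pixel intensities map proportionally onto input rates", {
  expect_equal(rates_from_image(c(0, 0.5, 1), 0.2), c(0, 0.1, 0.2))
  expect_equal(rates_from_image(1, 0.2) * 1000, 200)   # phi_max in Hz
  expect_error(rates_from_image(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("IDX files round-trip and malformed headers are rejected", {
  set.seed(55)
  d <- synthetic_dataset(3, 12, 5, noise_sd = 0.05)
  d$images[] <- sample(0:255, length(d$images), replace = TRUE) / 255
  ip <- tempfile(); lp <- tempfile()
  write_idx(d, ip, lp, rows = 3, cols = 4)
  back <- read_idx(ip, lp)
  expect_equal(back$images, d$images, ignore_attr = TRUE)
  expect_identical(back$labels, d$labels)
  # swapped files have the wrong magic numbers
  expect_error(read_idx(lp, ip), "magic")
  # label count mismatch
  d2 <- d; d2$images <- d$images[1:10, ]; d2$labels <- d$labels[1:10]
  lp2 <- tempfile()
  write_idx(d2, tempfile(), lp2, rows = 3, cols = 4)
  expect_error(read_idx(ip, lp2), "mismatch")
})

test_that("runs persist, hash and resume deterministically", {
  set.seed(56)
  net <- dendrite_network(6, hidden = 4, n_classes = 3)
  dir1 <- tempfile()
  m1 <- persist_run(net, dir1, metrics = data.frame(epoch = 1, err = 50),
                    config = list(note = "a"))
  back <- load_run(dir1)
  expect_identical(back$net$W, net$W)
  expect_equal(back$metrics$err, 50)
  # manifest hash changes iff contents change
  net2 <- net; net2$W[[1]][1, 1] <- net2$W[[1]][1, 1] + 1
  dir2 <- tempfile()
  m2 <- persist_run(net2, dir2, metrics = data.frame(epoch = 1, err = 50))
  md5 <- function(m, f) {
    for (e in m$files) if (e$file == f) return(e$md5)
  }
  expect_false(identical(md5(m1, "weights.rds"), md5(m2, "weights.rds")))
  expect_identical(md5(m1, "metrics.csv"), md5(m2, "metrics.csv"))
  # restoring the snapshot continues the RNG stream
  set.seed(57)
  persist_run(net, dir1)
  ahead <- runif(3)
  load_run(dir1, restore_rng = TRUE)
  expect_identical(runif(3), ahead)
})
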