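#' Train a segregated-dendrite network
#'
#' On-line training: each epoch shuffles the dataset and presents every
#' example once, running a forward phase (no teaching current) and a target
#' phase (teaching current on), and updating all feedforward weights at the
#' end of the target phase with the local, plateau-driven rules. Feedback
#' weights stay fixed (symmetric modes are refreshed from the feedforward
#' weights after each update). All randomness comes from the global R RNG
#' stream; the per-presentation order of draws is forward length, target
#' length, plateau offsets (stochastic mode only), then every spike.
#'
#' @param net A [dendrite_network()].
#' @param data A `dendrite_dataset` used for training.
#' @param epochs Number of passes over the data; with `epochs = 0` and a
#'   `test_data` set, only the initial evaluation is recorded.
#' @param eta Learning rates (hidden layers bottom-to-top, then output);
#'   defaults to [default_learning_rates()].
#' @param test_data Optional held-out `dendrite_dataset`; when supplied the
#'   network is evaluated before training and at the end of every epoch.
#' @param track_angle Also compute the backpropagation-oracle update each
#'   presentation and record the angle between it and the local update
#'   (one-hidden-layer networks only).
#' @param oracle_style Feedback style of the oracle, see
#'   [backprop_oracle_update()].
#' @param track_last Number of recent presentations whose mean hidden/output
#'   activity is kept as the operating point of the Jacobian monitor.
#' @param test_length Test-phase length (ms) for evaluations.
#' @param verbose Print a line per epoch.
#' @return A `dendrite_fit`: list with the trained `net`, per-`epochs`
#'   metrics (tibble: epoch, test error, mean losses, Jacobian eigenvalue),
#'   per-presentation records (`presentations` tibble with losses and
#'   angles), and the last-`track_last` operating points (`ops`).
#' @examples
#' set.seed(1)
#' d <- synthetic_dataset(3, 16, 20, noise_sd = 0.05)
#' net <- dendrite_network(16, hidden = 10, n_classes = 3)
#' fit <- train(net, d, epochs = 1)
#' tidy(fit)
#' @export
train <- function(net, data, epochs = 1, eta = NULL, test_data = NULL,
                  track_angle = FALSE, oracle_style = "spikes",
                  track_last = 100, test_length = 500, verbose = FALSE) {
  stopifnot(inherits(net, "dendrite_net"),
            inherits(data, "dendrite_dataset"))
  if (data$input_dim != net$input_dim ||
      data$n_classes > net$n_classes) {
    stop("dataset does not match the network architecture", call. = FALSE)
  }
  if (track_angle && net$n_hidden != 1) {
    stop("angle tracking needs a one-hidden-layer network", call. = FALSE)
  }
  eta <- eta %||% default_learning_rates(net$n_hidden)
  p <- net$params
  L <- net$n_hidden
  n_img <- nrow(data$images)
  n_pres <- epochs * n_img

  # per-presentation records
  rec_epoch <- integer(n_pres); rec_label <- integer(n_pres)
  rec_L1 <- numeric(n_pres)
  rec_L0 <- matrix(NA_real_, n_pres, max(L, 1))
  rec_angle <- rep(NA_real_, n_pres)

  # operating-point ring buffers for the Jacobian monitor
  m_last <- if (L > 0) net$hidden[L] else net$input_dim
  buf_h <- matrix(0, m_last, track_last)
  buf_o <- matrix(0, net$n_classes, track_last)
  buf_n <- 0L

  ep_rows <- list()
  add_epoch_row <- function(epoch, err) {
    idx <- rec_epoch == epoch & rec_epoch > 0
    mu <- if (L == 1 && buf_n > 0) {
      used <- min(buf_n, track_last)
      if (used < track_last) {
        warning("Jacobian operating point uses only ", used, " examples",
                call. = FALSE)
      }
      jacobian_product_eigenvalue(
        net$W[[L + 1]], net$Y[[L]]$Y,
        rowMeans(buf_h[, seq_len(used), drop = FALSE]),
        rowMeans(buf_o[, seq_len(used), drop = FALSE]), p,
        b1 = net$b[[L + 1]])
    } else NA_real_
    ep_rows[[length(ep_rows) + 1]] <<- tibble::tibble(
      epoch = epoch, test_error = err,
      mean_loss_output = if (any(idx)) mean(rec_L1[idx]) else NA_real_,
      mean_loss_hidden = if (any(idx) && L > 0) mean(rec_L0[idx, 1])
                         else NA_real_,
      jacobian_mu = mu)
  }

  if (!is.null(test_data)) {
    err0 <- evaluate(net, test_data, test_length = test_length)$error
    add_epoch_row(0L, err0)
    if (verbose) message("epoch 0: test error ", round(err0, 2), "%")
  }

  pres <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n_img)
    for (i in ord) {
      pres <- pres + 1L
      rates <- rates_from_image(data$images[i, ], p$phi_max)
      trial <- run_trial(net, rates, target_class = data$labels[i] + 1L,
                         mode = "train")
      ls <- losses(trial, net)
      grads <- vector("list", L + 1)
      for (k in seq_len(L)) grads[[k]] <- hidden_gradients(trial, net, k)
      grads[[L + 1]] <- output_gradients(trial, net)
      if (track_angle) {
        bp <- backprop_oracle_update(net, trial,
                                     feedback_style = oracle_style)
        rec_angle[pres] <- update_angle(grads[[1]]$dW, bp$dW)
      }
      net <- apply_updates(net, grads, eta)

      rec_epoch[pres] <- epoch
      rec_label[pres] <- data$labels[i]
      rec_L1[pres] <- ls$output
      if (L > 0) rec_L0[pres, seq_len(L)] <- ls$hidden
      slot <- (pres - 1L) %% track_last + 1L
      buf_h[, slot] <- if (L > 0)
        trial$forward$s[[paste0("hidden", L)]] else trial$forward$s$input
      buf_o[, slot] <- trial$forward$phi$output
      buf_n <- buf_n + 1L
    }
    err <- if (!is.null(test_data)) {
      evaluate(net, test_data, test_length = test_length)$error
    } else NA_real_
    add_epoch_row(epoch, err)
    if (verbose) {
      message("epoch ", epoch, ": mean L1 ",
              signif(mean(rec_L1[rec_epoch == epoch]), 3),
              if (!is.na(err)) paste0(", test error ", round(err, 2), "%"))
    }
  }

  presentations <- tibble::tibble(
    presentation = seq_len(n_pres),
    epoch = rec_epoch, label = rec_label,
    loss_output = rec_L1)
  if (L > 0) {
    for (k in seq_len(L)) {
      presentations[[paste0("loss_hidden", k)]] <- rec_L0[, k]
    }
  }
  presentations$angle <- rec_angle

  used <- min(buf_n, track_last)
  structure(
    list(net = net,
         epochs = if (length(ep_rows)) dplyr::bind_rows(ep_rows)
                  else tibble::tibble(),
         presentations = presentations,
         ops = list(
           hidden = if (used > 0) rowMeans(buf_h[, seq_len(used),
                                                 drop = FALSE]) else NULL,
           output = if (used > 0) rowMeans(buf_o[, seq_len(used),
                                                 drop = FALSE]) else NULL,
           n = used),
         eta = eta, n_epochs = epochs),
    class = "dendrite_fit"
  )
}

#' @export
print.dendrite_fit <- function(x, ...) {
  cat("<dendrite_fit> ", paste(x$net$sizes, collapse = "-"), ", ",
      x$n_epochs, " epoch(s), ", nrow(x$presentations),
      " presentations\n", sep = "")
  if (nrow(x$epochs)) {
    err <- x$epochs$test_error[nrow(x$epochs)]
    if (!is.na(err)) cat("  final test error: ", round(err, 2), "%\n",
                         sep = "")
  }
  invisible(x)
}

#' Evaluate classification error
#'
#' Runs a single fixed-length forward phase per example (no teaching
#' current) and classifies by the output unit with the greatest
#' time-averaged somatic potential (equivalently the greatest average rate);
#' ties break toward the lowest unit index. Error is the percentage of
#' misclassified examples.
#'
#' @param net A `dendrite_net`.
#' @param data A `dendrite_dataset`.
#' @param test_length Forward-phase length (ms).
#' @return A list with `error` (percentage) and a `predictions` tibble
#'   (`label`, `predicted`, `correct`).
#' @export
evaluate <- function(net, data, test_length = 500) {
  stopifnot(inherits(net, "dendrite_net"),
            inherits(data, "dendrite_dataset"))
  n <- nrow(data$images)
  if (n == 0) stop("empty dataset", call. = FALSE)
  pred <- integer(n)
  for (i in seq_len(n)) {
    rates <- rates_from_image(data$images[i, ], net$params$phi_max)
    trial <- run_trial(net, rates, mode = "test",
                       test_length = test_length)
    pred[i] <- which.max(trial$forward$v$output) - 1L
  }
  correct <- pred == data$labels
  list(error = 100 * mean(!correct),
       predictions = tibble::tibble(label = data$labels, predicted = pred,
                                    correct = correct))
}

#' Repeated stochastic weight tests
#'
#' Re-evaluates fixed weights `n` times under fresh spiking noise, reporting
#' each error plus the mean and min-max spread. The spread reflects Poisson
#' variability in the test phases and shrinks as `test_length` grows.
#'
#' @param net A `dendrite_net`.
#' @param data A `dendrite_dataset`.
#' @param n Number of repeated tests (>= 2).
#' @param test_length Forward-phase length (ms).
#' @return A tibble with columns `test`, `error`; attributes `mean`, `min`,
#'   `max`.
#' @export
repeated_tests <- function(net, data, n = 20, test_length = 500) {
  stopifnot(n >= 2)
  errs <- vapply(seq_len(n), function(i) {
    evaluate(net, data, test_length = test_length)$error
  }, numeric(1))
  out <- tibble::tibble(test = seq_len(n), error = errs)
  attr(out, "mean") <- mean(errs)
  attr(out, "min") <- min(errs)
  attr(out, "max") <- max(errs)
  out
}

#' Run a grid of training experiments
#'
#' Trains one network per grid cell (architecture depth, feedback mode,
#' apical conductance, plateau mode, seed), each cell fully seeded: the
#' synthetic dataset, initial weights and every spike derive from the cell's
#' seed. Failures are isolated per cell.
#'
#' @param cells A data frame with any of the columns `seed`, `hidden`
#'   (list-column of integer vectors, or a single integer; `0` or empty for
#'   the shallow network), `feedback`, `g_a`, `plateau`, `epochs`.
#' @param n_classes,input_dim,n_train_per_class,n_test_per_class,noise_sd
#'   Synthetic-task parameters shared by all cells.
#' @param epochs Default number of epochs for cells that do not set one.
#' @param test_length Test-phase length (ms).
#' @param keep_fits Keep each cell's full fit object in a list-column.
#' @return The grid tibble with added `error` (final test error, `NA` on
#'   failure), `message`, and optionally `fit` columns.
#' @export
experiment_grid <- function(cells, n_classes = 10, input_dim = 64,
                            n_train_per_class = 200, n_test_per_class = 100,
                            noise_sd = 0.08, epochs = 3, test_length = 500,
                            keep_fits = FALSE) {
  cells <- tibble::as_tibble(cells)
  n <- nrow(cells)
  get_col <- function(nm, default) {
    if (nm %in% names(cells)) cells[[nm]] else rep(default, n)
  }
  seeds <- get_col("seed", seq_len(n))
  feedbacks <- get_col("feedback", "random")
  gas <- get_col("g_a", 0)
  plateaus <- get_col("plateau", "synchronized")
  eps <- get_col("epochs", epochs)
  hiddens <- if ("hidden" %in% names(cells)) cells$hidden
             else rep(list(100L), n)
  if (!is.list(hiddens)) hiddens <- as.list(hiddens)

  res <- purrr::map(seq_len(n), function(i) {
    tryCatch({
      set.seed(seeds[[i]])
      tr <- synthetic_dataset(n_classes, input_dim, n_train_per_class,
                              noise_sd)
      te <- synthetic_dataset(n_classes, input_dim, n_test_per_class,
                              noise_sd, check_separability = FALSE,
                              prototypes = tr$prototypes)
      h <- hiddens[[i]]
      h <- h[h > 0]
      net <- dendrite_network(input_dim, hidden = h, n_classes = n_classes,
                              params = neuron_params(g_a = gas[[i]]),
                              feedback = feedbacks[[i]],
                              plateau = plateaus[[i]])
      fit <- train(net, tr, epochs = eps[[i]])
      err <- evaluate(fit$net, te, test_length = test_length)$error
      list(error = err, message = "ok", fit = if (keep_fits) fit else NULL)
    }, error = function(e) {
      list(error = NA_real_, message = conditionMessage(e), fit = NULL)
    })
  })
  cells$seed <- unlist(seeds)
  cells$error <- vapply(res, `[[`, numeric(1), "error")
  cells$message <- vapply(res, `[[`, character(1), "message")
  if (keep_fits) cells$fit <- lapply(res, `[[`, "fit")
  cells
}
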