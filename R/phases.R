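# Inverse-Gaussian (Wald) sampler, Michael-Schucany-Haas transform.
rwald <- function(n, mean = 2, shape = 1) {
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Sample a training-phase length
#'
#' Phase lengths are a 50 ms minimum plus an extra time drawn from a Wald
#' (inverse Gaussian) distribution with mean 2 ms and shape 1, sampled
#' independently for the forward and target phases of every example.
#'
#' @param n Number of draws.
#' @param min_ms Minimum phase length (ms).
#' @param mean,shape Wald parameters of the extra time (ms).
#' @return Phase duration(s) in ms (continuous; the simulator rounds to the
#'   nearest time step).
#' @export
sample_phase_length <- function(n = 1, min_ms = 50, mean = 2, shape = 1) {
  min_ms + rwald(n, mean, shape)
}

#' Sample per-neuron plateau-time offsets
#'
#' In the stochastic-plateau variant each hidden neuron computes its plateau
#' potential at its own time, 0-5 ms before phase end: offsets are drawn
#' from a folded normal (mu = 0, sigma^2 = 3) truncated at 5 ms.
#'
#' @param n_neurons Number of hidden neurons.
#' @param sigma2 Variance of the underlying normal.
#' @param max_ms Truncation point (ms).
#' @return Offsets in `[0, max_ms]` (ms before phase end).
#' @export
sample_plateau_times <- function(n_neurons, sigma2 = 3, max_ms = 5) {
  x <- abs(stats::rnorm(n_neurons, 0, sqrt(sigma2)))
  while (any(x > max_ms)) {
    bad <- x > max_ms
    x[bad] <- abs(stats::rnorm(sum(bad), 0, sqrt(sigma2)))
  }
  x
}

#' Plateau potentials from an apical voltage history
#'
#' A plateau potential is the sigmoid of the time-averaged apical voltage.
#' In synchronized mode the average runs over the post-settle window
#' `[settle+1, n]` (the discrete mean stands in for the integral, dt = 1 ms).
#' With per-neuron `offsets` (stochastic mode) neuron i averages the
#' `window` ms ending `round(offsets[i])` ms before phase end; that window
#' may reach back into the settle period but not before the phase start.
#'
#' @param apical_history steps x neurons matrix of apical voltages over one
#'   phase.
#' @param settle Settling time (steps) excluded in synchronized mode.
#' @param offsets Optional per-neuron offsets (ms before phase end).
#' @param window Averaging window (ms) in stochastic mode.
#' @return Vector of plateau values in (0, 1).
#' @export
compute_plateaus <- function(apical_history, settle = 30, offsets = NULL,
                             window = 30) {
  apical_history <- as.matrix(apical_history)
  n <- nrow(apical_history)
  if (is.null(offsets)) {
    if (n <= settle) stop("phase has no post-settle steps", call. = FALSE)
    return(sigmoid(colMeans(apical_history[(settle + 1):n, , drop = FALSE])))
  }
  stopifnot(length(offsets) == ncol(apical_history))
  off <- as.integer(round(offsets))
  vapply(seq_along(off), function(i) {
    hi <- n - off[i]
    lo <- max(1L, hi - window + 1L)
    if (hi < 1) stop("plateau offset exceeds phase length", call. = FALSE)
    sigmoid(mean(apical_history[lo:hi, i]))
  }, numeric(1))
}

# parameter list handed to the compiled engine
engine_par <- function(net) {
  p <- net$params
  list(g_l = p$g_l, g_b = p$g_b, g_a = p$g_a, g_d = p$g_d, c_m = p$c_m,
       v_r = p$v_r, phi_max = p$phi_max, dt = p$dt,
       tau_l = p$kernel$tau_l, tau_s = p$kernel$tau_s,
       e_e = p$e_e, e_i = p$e_i,
       teach_literal = identical(p$teach_scale, "literal"),
       apical_rates = identical(net$apical_feedback, "rates"))
}

name_phase <- function(ph, net) {
  if (is.null(ph)) return(NULL)
  L <- net$n_hidden
  lname <- c(if (L > 0) paste0("hidden", seq_len(L)), "output")
  names(ph$v) <- lname
  names(ph$phi) <- lname
  names(ph$s) <- c("input", lname)
  if (L > 0) {
    names(ph$va) <- lname[seq_len(L)]
    names(ph$va_hist) <- lname[seq_len(L)]
  }
  ph$v <- lapply(ph$v, drop)
  ph$phi <- lapply(ph$phi, drop)
  ph$s <- lapply(ph$s, drop)
  ph$va <- lapply(ph$va, drop)
  ph
}

#' Run one stimulus trial
#'
#' Presents one input-rate vector to the network. In `"train"` mode the
#' network undergoes a forward phase (no teaching current) and a target
#' phase (teaching current clamping the output layer), each with its own
#' sampled duration; plateau potentials are computed at the end of each
#' phase from the apical voltage history. In `"test"` mode a single fixed
#' 500 ms forward phase is run and only its time averages are returned.
#' The network state starts from rest each trial; averages exclude the
#' first `settle` ms of each phase.
#'
#' Randomness (phase lengths, plateau offsets if stochastic, and every spike)
#' is consumed from the global R RNG stream in a fixed documented order, so a
#' trial is fully reproducible under `set.seed()`.
#'
#' @param net A [dendrite_network()].
#' @param input_rates Input firing rates (spikes/ms), length `input_dim`,
#'   within `[0, phi_max]`.
#' @param target_class 1-based index of the correct output unit (train mode);
#'   `NULL` runs the target phase without any teaching current (used by
#'   control analyses).
#' @param mode `"train"` or `"test"`.
#' @param steps_forward,steps_target Optional fixed phase lengths (steps);
#'   sampled via [sample_phase_length()] when missing in train mode.
#' @param test_length Forward-phase length in test mode (ms).
#' @param keep_history Keep the full apical voltage histories on the record.
#' @return A `dendrite_trial` record with per-phase time averages (`v`,
#'   `phi`, `s`, `va` per layer), plateau values `alpha_f`/`alpha_t` per
#'   hidden layer, and phase lengths.
#' @export
run_trial <- function(net, input_rates, target_class = NULL,
                      mode = c("train", "test"),
                      steps_forward = NULL, steps_target = NULL,
                      test_length = 500, keep_history = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "dendrite_net"))
  p <- net$params
  if (length(input_rates) != net$input_dim) {
    stop("input_rates length does not match the input layer", call. = FALSE)
  }
  if (any(input_rates < 0) || any(input_rates > p$phi_max + 1e-12)) {
    stop("input rates must lie in [0, phi_max]", call. = FALSE)
  }
  if (!is.null(target_class) &&
      (target_class < 1 || target_class > net$n_classes)) {
    stop("target_class out of range", call. = FALSE)
  }

  settle <- as.integer(round(p$settle / p$dt))
  if (mode == "test") {
    sf <- as.integer(round(test_length / p$dt))
    st <- 0L
  } else {
    sf <- steps_forward %||% as.integer(round(sample_phase_length() / p$dt))
    st <- steps_target %||% as.integer(round(sample_phase_length() / p$dt))
  }
  if (sf <= settle || (st > 0 && st <= settle)) {
    stop("phase shorter than the settling time", call. = FALSE)
  }

  stochastic <- identical(net$plateau, "stochastic") && net$n_hidden > 0
  off_f <- off_t <- NULL
  if (mode == "train" && stochastic) {
    off_f <- lapply(net$hidden, sample_plateau_times)
    off_t <- lapply(net$hidden, sample_plateau_times)
  }

  Ylist <- lapply(net$Y, `[[`, "Y")
  res <- .trial_engine(net$W, net$b, Ylist, input_rates,
                       if (is.null(target_class)) -1L
                       else as.integer(target_class - 1L),
                       sf, st, settle, engine_par(net))

  fwd <- name_phase(res$forward, net)
  tgt <- name_phase(res$target, net)

  plateaus <- NULL
  if (mode == "train" && net$n_hidden > 0) {
    plateaus <- lapply(seq_len(net$n_hidden), function(k) {
      list(
        alpha_f = compute_plateaus(fwd$va_hist[[k]], settle,
                                   offsets = off_f[[k]]),
        alpha_t = compute_plateaus(tgt$va_hist[[k]], settle,
                                   offsets = off_t[[k]])
      )
    })
    names(plateaus) <- paste0("hidden", seq_len(net$n_hidden))
  }
  if (!keep_history) {
    fwd$va_hist <- NULL
    if (!is.null(tgt)) tgt$va_hist <- NULL
  }

  structure(
    list(mode = mode, target_class = target_class,
         forward = fwd, target = tgt, plateaus = plateaus,
         input_rates = input_rates,
         steps = c(forward = sf, target = st)),
    class = "dendrite_trial"
  )
}

#' @export
print.dendrite_trial <- function(x, ...) {
  cat("<dendrite_trial> mode =", x$mode,
      "| forward", x$steps[["forward"]], "ms")
  if (x$steps[["target"]] > 0) cat(" | target", x$steps[["target"]], "ms")
  cat("\n")
  invisible(x)
}
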