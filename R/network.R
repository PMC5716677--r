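#' Initialise a layer's feedforward weights
#'
#' Weights are drawn uniformly over
#' `[-6/(fan_in * phi_max), 12/(fan_in * phi_max)]` so that whenever all
#' presynaptic traces are at most `phi_max` the dendritic voltage is
#' guaranteed to lie in `[-6, 12]`. Biases start at 0.
#'
#' @param n_out Number of postsynaptic units.
#' @param n_in Fan-in (number of presynaptic units).
#' @param phi_max Maximum firing rate (spikes/ms).
#' @return A list with matrix `W` (`n_out x n_in`) and vector `b`.
#' @export
init_weights <- function(n_out, n_in, phi_max = 0.2) {
  stopifnot(n_out >= 1, n_in >= 1, phi_max > 0)
  lo <- -6 / (n_in * phi_max)
  hi <- 12 / (n_in * phi_max)
  list(W = matrix(stats::runif(n_out * n_in, lo, hi), n_out, n_in),
       b = numeric(n_out))
}

#' Construct feedback weights for a hidden layer
#'
#' Feedback from the output layer to a hidden layer's apical dendrites.
#' Modes:
#' \describe{
#'   \item{random}{fixed uniform draw with the same calibration as
#'     [init_weights()] (feedback fan-in = number of output units).}
#'   \item{sparse}{the random draw with `ceiling(0.8 * length)` entries set
#'     to zero and the survivors multiplied by five.}
#'   \item{symmetric}{the transpose of the feedforward weights above,
#'     refreshed after every weight update.}
#'   \item{symmetric_noise}{symmetric plus a fixed Gaussian perturbation
#'     (sd 0.05 by default) drawn once at construction and re-added at each
#'     refresh.}
#' }
#'
#' @param W_above Feedforward weight matrix of the layer above
#'   (`n_above x n_hidden`).
#' @param mode One of `"random"`, `"sparse"`, `"symmetric"`,
#'   `"symmetric_noise"`.
#' @param phi_max Maximum firing rate (spikes/ms), used by the uniform
#'   calibration.
#' @param noise_sd Scale of the symmetric-noise perturbation.
#' @param noise_as Whether `noise_sd` is a standard deviation (default) or a
#'   variance.
#' @return A list with the feedback matrix `Y` (`n_hidden x n_above`), the
#'   `mode`, and for `symmetric_noise` the fixed `noise` matrix.
#' @export
make_feedback <- function(W_above, mode = c("random", "sparse", "symmetric",
                                            "symmetric_noise"),
                          phi_max = 0.2, noise_sd = 0.05,
                          noise_as = c("sd", "variance")) {
  mode <- match.arg(mode)
  noise_as <- match.arg(noise_as)
  n_above <- nrow(W_above)
  n_hidden <- ncol(W_above)
  fb <- list(mode = mode, noise = NULL)
  if (mode %in% c("random", "sparse")) {
    lo <- -6 / (n_above * phi_max)
    hi <- 12 / (n_above * phi_max)
    Y <- matrix(stats::runif(n_hidden * n_above, lo, hi), n_hidden, n_above)
    if (mode == "sparse") {
      nzero <- ceiling(0.8 * length(Y))
      Y[sample.int(length(Y), nzero)] <- 0
      Y <- Y * 5
    }
    fb$Y <- Y
  } else {
    if (mode == "symmetric_noise") {
      sd <- if (noise_as == "variance") sqrt(noise_sd) else noise_sd
      fb$noise <- matrix(stats::rnorm(n_hidden * n_above, 0, sd),
                         n_hidden, n_above)
    }
    fb$Y <- refresh_feedback(fb, W_above)$Y
  }
  fb
}

# re-derive symmetric-type feedback from the current feedforward weights;
# random/sparse feedback is fixed for the whole run
refresh_feedback <- function(fb, W_above) {
  if (fb$mode == "symmetric") {
    fb$Y <- t(W_above)
  } else if (fb$mode == "symmetric_noise") {
    fb$Y <- t(W_above) + fb$noise
  }
  fb
}

#' Build a segregated-dendrite network
#'
#' Creates a network with `length(hidden)` hidden layers of three-compartment
#' neurons (basal, apical, somatic) and an output layer of two-compartment
#' neurons, one per class. Every hidden layer receives feedback from the
#' output layer through its own fixed matrix, so no backward pass through
#' intermediate layers is ever needed. Weights are drawn from the current R
#' RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param input_dim Number of input (Poisson) units.
#' @param hidden Integer vector of hidden layer sizes; `integer(0)` or `NULL`
#'   builds a shallow network whose inputs project directly to the output
#'   layer.
#' @param n_classes Number of output units.
#' @param params A [neuron_params()] object.
#' @param feedback Feedback-weight mode, see [make_feedback()].
#' @param plateau `"synchronized"` computes every neuron's plateau potential
#'   from the full post-settle phase window; `"stochastic"` gives each neuron
#'   its own plateau time 0-5 ms before phase end and a 30 ms window.
#' @param target_baseline Baseline used in hidden-layer targets: the
#'   forward-phase average rate (default) or the target-phase average.
#' @param apical_feedback Whether apical dendrites are driven by the filtered
#'   output spike trains (`"spikes"`, default) or directly by the output
#'   rates (`"rates"`), the noiseless feedback variant.
#' @return An object of class `dendrite_net`.
#' @examples
#' set.seed(1)
#' net <- dendrite_network(16, hidden = 8, n_classes = 3)
#' net
#' @export
dendrite_network <- function(input_dim, hidden = 100, n_classes = 10,
                             params = neuron_params(),
                             feedback = c("random", "sparse", "symmetric",
                                          "symmetric_noise"),
                             plateau = c("synchronized", "stochastic"),
                             target_baseline = c("forward", "target"),
                             apical_feedback = c("spikes", "rates")) {
  feedback <- match.arg(feedback)
  plateau <- match.arg(plateau)
  target_baseline <- match.arg(target_baseline)
  apical_feedback <- match.arg(apical_feedback)
  hidden <- as.integer(hidden %||% integer(0))
  stopifnot(input_dim >= 1, n_classes >= 2, all(hidden >= 1))

  sizes <- c(input_dim, hidden, n_classes)
  n_layers <- length(sizes) - 1L          # trainable layers
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    init <- init_weights(sizes[k + 1], sizes[k], params$phi_max)
    W[[k]] <- init$W
    b[[k]] <- init$b
  }
  Y <- vector("list", length(hidden))
  for (k in seq_along(hidden)) {
    # every hidden layer is fed back from the output layer; the symmetric
    # modes only make sense for the layer directly below the output
    W_ref <- if (k == length(hidden)) W[[n_layers]] else
      matrix(0, n_classes, hidden[k])
    mode_k <- if (feedback %in% c("symmetric", "symmetric_noise") &&
                  k < length(hidden)) "random" else feedback
    Y[[k]] <- make_feedback(W_ref, mode_k, phi_max = params$phi_max)
  }

  structure(
    list(sizes = sizes, input_dim = input_dim, hidden = hidden,
         n_classes = n_classes, n_hidden = length(hidden),
         W = W, b = b, Y = Y, params = params,
         feedback = feedback, plateau = plateau,
         target_baseline = target_baseline,
         apical_feedback = apical_feedback),
    class = "dendrite_net"
  )
}

#' @export
print.dendrite_net <- function(x, ...) {
  arch <- paste(x$sizes, collapse = "-")
  cat("<dendrite_net> ", arch, "\n", sep = "")
  cat("  hidden layers: ", x$n_hidden,
      " | feedback: ", x$feedback,
      " | g_a = ", x$params$g_a,
      " | plateaus: ", x$plateau, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
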