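#' Output-layer target rates
#'
#' The output target is the target-phase average firing rate vector
#' (the activity imposed by the teaching current).
#'
#' @param trial A train-mode `dendrite_trial`.
#' @return Target rate vector (spikes/ms).
#' @export
output_target <- function(trial) {
  if (is.null(trial$target)) {
    stop("trial has no target phase (test mode?)", call. = FALSE)
  }
  trial$target$phi$output
}

#' Hidden-layer target rates
#'
#' Hidden targets add the plateau-potential difference to a baseline rate:
#' `phi* = phibar_f + alpha_t - alpha_f` with the forward-phase average as
#' baseline (default), or the target-phase average under
#' `baseline = "target"`. Targets are not clipped to `[0, phi_max]` and are
#' treated as constants when differentiating the loss.
#'
#' @param trial A train-mode `dendrite_trial`.
#' @param layer Hidden layer index (1 = closest to the input).
#' @param baseline `"forward"` or `"target"`.
#' @return Target rate vector (spikes/ms).
#' @export
hidden_target <- function(trial, layer = 1,
                          baseline = c("forward", "target")) {
  baseline <- match.arg(baseline)
  pl <- trial$plateaus[[layer]]
  if (is.null(pl)) stop("trial has no plateau potentials", call. = FALSE)
  key <- paste0("hidden", layer)
  base <- if (baseline == "forward") trial$forward$phi[[key]]
          else trial$target$phi[[key]]
  base + pl$alpha_t - pl$alpha_f
}

#' Local loss functions
#'
#' Exact local losses: `L1 = ||phi1* - phi_max sigma(Vbar_1^f)||^2` at the
#' output layer and `L0 = ||phi0* - phi_max sigma(Vbar_0^f)||^2` per hidden
#' layer, using the sigmoid of the mean forward voltage (not the mean rate).
#' When the rates sit in the sigmoid's linear region `L0` is approximately
#' `||alpha_t - alpha_f||^2`.
#'
#' @param trial A train-mode `dendrite_trial`.
#' @param net The network the trial was run on.
#' @return A list with scalar `output` and numeric vector `hidden` (one loss
#'   per hidden layer; length 0 for shallow networks).
#' @export
losses <- function(trial, net) {
  p <- net$params
  phi1s <- output_target(trial)
  L1 <- sum((phi1s - p$phi_max * sigmoid(trial$forward$v$output))^2)
  Lh <- numeric(net$n_hidden)
  for (k in seq_len(net$n_hidden)) {
    tgt <- hidden_target(trial, k, baseline = net$target_baseline)
    key <- paste0("hidden", k)
    Lh[k] <- sum((tgt - p$phi_max * sigmoid(trial$forward$v[[key]]))^2)
  }
  list(output = L1, hidden = Lh)
}

#' Output-layer gradients
#'
#' Delta-rule gradient of the output loss with respect to the output weights
#' and biases (half-squared-error convention):
#' `dW1 = -k_d phi_max (phi1* - phi_max sigma(Vbar1f)) sigma'(Vbar1f) %o% sbar_pre^f`,
#' the bias gradient omitting the presynaptic-trace factor. Target-phase
#' activity is treated as fixed.
#'
#' @param trial A train-mode `dendrite_trial`.
#' @param net The network.
#' @return A list with `dW` and `db`.
#' @export
output_gradients <- function(trial, net) {
  p <- net$params
  k_d <- attenuation_factors(p)$k_d
  v1 <- trial$forward$v$output
  err <- output_target(trial) - p$phi_max * sigmoid(v1)
  pre_key <- if (net$n_hidden > 0) paste0("hidden", net$n_hidden) else "input"
  s_pre <- trial$forward$s[[pre_key]]
  db <- -k_d * p$phi_max * err * sigmoid_prime(v1)
  list(dW = db %o% s_pre, db = db)
}

#' Hidden-layer gradients
#'
#' The spatially local learning rule: plateau-potential difference times the
#' rate-function derivative, outer-multiplied with the layer's own mean
#' presynaptic traces,
#' `dW0 = -k_b (alpha_t - alpha_f) phi_max sigma'(Vbar0f) %o% sbar_input^f`.
#' Only quantities local to the hidden layer enter: its plateaus, its mean
#' forward somatic voltage and its presynaptic traces.
#'
#' @param trial A train-mode `dendrite_trial`.
#' @param net The network.
#' @param layer Hidden layer index.
#' @return A list with `dW` and `db`.
#' @export
hidden_gradients <- function(trial, net, layer = 1) {
  p <- net$params
  k_b <- attenuation_factors(p)$k_b
  pl <- trial$plateaus[[layer]]
  if (is.null(pl)) stop("trial has no plateau potentials", call. = FALSE)
  key <- paste0("hidden", layer)
  v0 <- trial$forward$v[[key]]
  pre_key <- if (layer == 1) "input" else paste0("hidden", layer - 1)
  s_pre <- trial$forward$s[[pre_key]]
  db <- -k_b * (pl$alpha_t - pl$alpha_f) * p$phi_max * sigmoid_prime(v0)
  list(dW = db %o% s_pre, db = db)
}

#' Apply gradient-descent updates
#'
#' `W <- W - eta * P * dW` per layer, with `P = 20/phi_max` for hidden
#' layers and `20/phi_max^2` for the output layer; biases use the same
#' scaling. Updates are applied once, at the end of a target phase.
#' Symmetric-type feedback matrices are refreshed from the new feedforward
#' weights.
#'
#' @param net The network.
#' @param updates List of per-layer gradients (each a list `dW`, `db`),
#'   ordered hidden layers bottom-to-top then the output layer.
#' @param eta Learning-rate vector in the same order (recycled if scalar).
#' @return The updated network.
#' @export
apply_updates <- function(net, updates, eta) {
  n_layers <- length(net$W)
  stopifnot(length(updates) == n_layers)
  eta <- rep_len(eta, n_layers)
  sc <- error_scaling(net$params$phi_max)
  P <- c(rep(sc$P0, net$n_hidden), sc$P1)
  for (k in seq_len(n_layers)) {
    u <- updates[[k]]
    if (is.null(u)) next
    if (!all(is.finite(u$dW)) || !all(is.finite(u$db))) {
      stop("non-finite weight update in layer ", k, call. = FALSE)
    }
    net$W[[k]] <- net$W[[k]] - eta[k] * P[k] * u$dW
    net$b[[k]] <- net$b[[k]] - eta[k] * P[k] * u$db
  }
  if (net$n_hidden > 0) {
    k <- net$n_hidden
    net$Y[[k]] <- refresh_feedback(net$Y[[k]], net$W[[net$n_hidden + 1]])
  }
  net
}

#' Default learning rates by depth
#'
#' 0.19 for the shallow network, 0.21/0.21 for one hidden layer, and
#' 0.23/0.23 (hidden) with 0.12 (output) for two hidden layers.
#'
#' @param n_hidden Number of hidden layers (0, 1 or 2).
#' @return Learning-rate vector ordered hidden layers then output.
#' @export
default_learning_rates <- function(n_hidden) {
  switch(as.character(n_hidden),
         "0" = 0.19,
         "1" = c(0.21, 0.21),
         "2" = c(0.23, 0.23, 0.12),
         rep(0.2, n_hidden + 1))
}

#' Backpropagation oracle update
#'
#' The hidden-layer gradient that exact backpropagation of the output loss
#' through the deterministic two-layer rate model
#' `phi_max sigma(k_d W1 phi_max sigma(k_b W0 x + b0) + b1)` would
#' prescribe: the output error term is sent back through `t(W1)`, modulated
#' by `k_b phi_max sigma'(Vbar0f)` and outer-multiplied with the mean input
#' traces. Used only for comparison with the local rule (never for
#' learning). `feedback_style = "spikes"` takes the output activity as
#' measured in the trial (driven by hidden spike trains);
#' `"rates"` recomputes it noiselessly from the mean hidden rates,
#' `V1 = k_d (W1 phibar0f + b1)`.
#'
#' @param net A one-hidden-layer network.
#' @param trial A train-mode `dendrite_trial`.
#' @param feedback_style `"spikes"` or `"rates"`.
#' @return A list with `dW` (and `db`) for the hidden layer.
#' @export
backprop_oracle_update <- function(net, trial,
                                   feedback_style = c("spikes", "rates")) {
  feedback_style <- match.arg(feedback_style)
  if (net$n_hidden != 1) {
    stop("the backprop oracle supports one-hidden-layer networks only",
         call. = FALSE)
  }
  p <- net$params
  att <- attenuation_factors(p)
  phi1s <- output_target(trial)
  v1 <- if (feedback_style == "spikes") trial$forward$v$output
        else att$k_d * drop(net$W[[2]] %*% trial$forward$phi$hidden1 +
                              net$b[[2]])
  e1 <- att$k_d * p$phi_max * (phi1s - p$phi_max * sigmoid(v1)) *
    sigmoid_prime(v1)
  v0 <- trial$forward$v$hidden1
  delta0 <- drop(crossprod(net$W[[2]], e1)) * att$k_b * p$phi_max *
    sigmoid_prime(v0)
  list(dW = -delta0 %o% trial$forward$s$input, db = -delta0)
}
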