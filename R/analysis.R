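#' Angle between two weight updates
#'
#' Arc-cosine of the cosine similarity between the flattened weight
#' matrices, in degrees. Bias terms are excluded by convention; two
#' independent high-dimensional updates sit near 90 degrees, so angles
#' persistently below 90 indicate that two learning rules point their
#' updates in a similar direction.
#'
#' @param dW_local,dW_bp Weight-update (or gradient) matrices of equal shape.
#' @return Angle in `[0, 180]` degrees.
#' @export
update_angle <- function(dW_local, dW_bp) {
  a <- as.numeric(dW_local)
  b <- as.numeric(dW_bp)
  if (length(a) != length(b)) stop("shape mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("angle undefined for a zero-norm update", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Sliding-window mean
#'
#' Trailing mean over the previous `window` observations (shorter at the
#' start of the series), used to smooth per-presentation angle series.
#'
#' @param x Numeric vector.
#' @param window Window length in observations.
#' @return Vector of windowed means, same length as `x`.
#' @export
sliding_mean <- function(x, window = 100) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0, i - window)
  (cs[i + 1] - cs[lo + 1]) / (i - lo)
}

#' Receptive-field similarity against a reference
#'
#' For every row (receptive field) of `W_local`, the maximum Pearson
#' correlation against all rows of `W_bp`, plus a control in which each
#' local field's entries are randomly permuted before matching (permutation
#' destroys spatial structure, so the control locates the chance level).
#'
#' @param W_local,W_bp Weight matrices with the same input dimensionality.
#' @return A tibble with columns `field`, `r_max`, `r_shuffled`
#'   (`NA` for constant fields).
#' @export
receptive_field_similarity <- function(W_local, W_bp) {
  if (ncol(W_local) != ncol(W_bp)) {
    stop("input dimensionality differs", call. = FALSE)
  }
  max_cor <- function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    ok <- apply(W_bp, 1, stats::sd) > 0
    if (!any(ok)) return(NA_real_)
    max(stats::cor(v, t(W_bp[ok, , drop = FALSE])))
  }
  real <- apply(W_local, 1, max_cor)
  shuf <- apply(W_local, 1, function(v) max_cor(sample(v)))
  tibble::tibble(field = seq_len(nrow(W_local)), r_max = real,
                 r_shuffled = shuf)
}

#' Hidden/output loss coordination
#'
#' Per-class Pearson correlation between the hidden-layer loss `L0` and the
#' output-layer loss `L1` across image presentations, together with a
#' shuffled-pairing control in which `L0` values are randomly re-paired with
#' `L1` values within the class. Correlations well above the control show
#' that reducing the local hidden loss also reduces the output loss, i.e.
#' that credit assignment is coordinated across layers.
#'
#' @param records A data frame with columns `label`, `loss_hidden1`,
#'   `loss_output` (e.g. the `presentations` table of a [train()] fit).
#' @return A tibble with columns `label`, `n`, `r`, `r_shuffled`.
#' @export
loss_correlation <- function(records) {
  stopifnot(all(c("label", "loss_hidden1", "loss_output") %in%
                  names(records)))
  records |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 3 && stats::sd(.data$loss_hidden1) > 0 &&
              stats::sd(.data$loss_output) > 0)
        stats::cor(.data$loss_hidden1, .data$loss_output) else NA_real_,
      r_shuffled = if (dplyr::n() >= 3 && stats::sd(.data$loss_hidden1) > 0 &&
                       stats::sd(.data$loss_output) > 0)
        stats::cor(sample(.data$loss_hidden1), .data$loss_output)
      else NA_real_,
      .groups = "drop"
    )
}

# largest eigenvalue of (I - Jb Jg)^T (I - Jb Jg)
jacobian_mu <- function(J_beta, J_gamma) {
  M <- diag(nrow(J_beta)) - J_beta %*% J_gamma
  max(eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values)
}

#' Jacobian-product eigenvalue monitor
#'
#' Numerical check of the loss-coordination condition: with
#' `beta(x) = phi_max sigma(k_d W1 x)` (forward transform of the hidden
#' activity) and `gamma(x) = sigma(Y x)` (feedback transform of the output
#' rates), coordination between the hidden and output losses is guaranteed
#' while the largest eigenvalue `mu` of
#' `(I - J_beta J_gamma)^T (I - J_beta J_gamma)` stays below 1. Jacobians
#' are evaluated at the elementwise mean activity of recent training
#' examples (typically the last 100).
#'
#' @param W1 Output-layer weight matrix (`n x m`).
#' @param Y Feedback matrix (`m x n`).
#' @param hidden_point Mean hidden activity vector (operating point of
#'   `beta`), e.g. the mean filtered hidden spike train.
#' @param output_point Mean output rate vector (operating point of `gamma`).
#' @param params A [neuron_params()] object.
#' @param b1 Output-layer bias vector; it enters the operating point so that
#'   `J_beta` is the Jacobian of the network's actual forward transform at
#'   its actual working voltages.
#' @return The largest eigenvalue `mu` (scalar).
#' @export
jacobian_product_eigenvalue <- function(W1, Y, hidden_point, output_point,
                                        params = neuron_params(),
                                        b1 = numeric(nrow(W1))) {
  k_d <- attenuation_factors(params)$k_d
  u <- k_d * drop(W1 %*% hidden_point + b1)
  J_beta <- params$phi_max * k_d * sigmoid_prime(u) * W1
  w <- drop(Y %*% output_point)
  J_gamma <- sigmoid_prime(w) * Y
  jacobian_mu(J_beta, J_gamma)
}

#' Settling bound of the firing-rate lemma
#'
#' The averaging window `Delta_t` must be much larger than
#' `2 tau_L^2 tau_s^2 phibar^2 / ((tau_L - tau_s)^2 (tau_L + tau_s))` for the
#' time-averaged filtered spike train to estimate the mean firing rate. At
#' the simulation parameters (tau_L = 10 ms, tau_s = 3 ms, 0.02 spikes/ms)
#' the bound is about 0.001, far below the 50 ms minimum phase length.
#'
#' @param tau_l,tau_s Kernel time constants (ms).
#' @param rate Mean firing rate (spikes/ms).
#' @return The bound (ms).
#' @export
lemma1_bound <- function(tau_l = 10, tau_s = 3, rate = 0.02) {
  2 * tau_l^2 * tau_s^2 * rate^2 / ((tau_l - tau_s)^2 * (tau_l + tau_s))
}

#' Monte-Carlo check of the firing-rate lemma
#'
#' Simulates independent Poisson spike trains, filters them with the
#' double-exponential kernel and compares the mean time-averaged trace with
#' the mean firing rate. By default the averaging window is preceded by a
#' burn-in so the filter is in its stationary regime, mirroring how the
#' network averages after a settling period; with `burn_in = 0` the window
#' starts cold and the average carries the lemma's edge deficit of about
#' `(tau_l + tau_s)/window` relative.
#'
#' @param rate Constant firing rate (spikes/ms) or a function of time (ms)
#'   returning the instantaneous rate.
#' @param window Averaging window (ms).
#' @param reps Number of independent repetitions.
#' @param kp A [kernel_params()] object.
#' @param dt Time step (ms).
#' @param burn_in Pre-window simulation time (ms).
#' @return A list with `mean_trace`, `rate` (the time-averaged target rate)
#'   and `rel_error`.
#' @export
lemma1_mc_check <- function(rate = 0.02, window = 500, reps = 1000,
                            kp = kernel_params(), dt = 1, burn_in = 100) {
  steps <- as.integer(round((burn_in + window) / dt))
  first <- as.integer(round(burn_in / dt)) + 1L
  rate_fn <- if (is.function(rate)) rate else function(t) rate
  dl <- exp(-dt / kp$tau_l); ds <- exp(-dt / kp$tau_s)
  sL <- numeric(reps); sS <- numeric(reps)
  acc <- numeric(reps)
  rbar <- 0
  for (t in seq_len(steps)) {
    r <- rate_fn(t * dt)
    sp <- as.numeric(stats::runif(reps) < r * dt)
    sL <- sL * dl + sp
    sS <- sS * ds + sp
    if (t >= first) {
      acc <- acc + (sL - sS) / (kp$tau_l - kp$tau_s)
      rbar <- rbar + r
    }
  }
  navg <- steps - first + 1L
  mean_trace <- mean(acc / navg)
  rbar <- rbar / navg
  list(mean_trace = mean_trace, rate = rbar,
       rel_error = abs(mean_trace - rbar) / rbar)
}
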