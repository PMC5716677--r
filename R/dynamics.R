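#' Dendritic compartment voltage
#'
#' Dendritic potentials are instantaneous weighted sums of the filtered
#' presynaptic spike trains: `V_d = W %*% trace + b`.
#'
#' @param W Weight matrix (units x presynaptic).
#' @param trace Filtered presynaptic trace vector.
#' @param b Bias vector (defaults to 0).
#' @return Dendritic voltage vector.
#' @export
dendrite_voltage <- function(W, trace, b = numeric(nrow(W))) {
  W <- as.matrix(W)
  if (ncol(W) != length(trace) || nrow(W) != length(b)) {
    stop("shape mismatch between weights, trace and bias", call. = FALSE)
  }
  drop(W %*% trace + b)
}

#' One Euler step of a hidden-layer soma
#'
#' Integrates
#' \eqn{\tau \dot V = (V_R - V) + (g_b/g_l)(V_b - V) + (g_a/g_l)(V_a - V)}
#' with forward Euler. With constant basal drive, `g_a = 0` and long
#' integration the voltage converges to `k_b * V_b`
#' (see [attenuation_factors()]).
#'
#' @param V Somatic voltage vector.
#' @param V_b Basal dendritic voltage vector.
#' @param V_a Apical dendritic voltage vector.
#' @param params A [neuron_params()] object.
#' @param dt Time step (ms).
#' @return Updated somatic voltage vector.
#' @export
step_hidden_soma <- function(V, V_b, V_a = numeric(length(V)),
                             params = neuron_params(), dt = params$dt) {
  stopifnot(length(V_b) == length(V), length(V_a) == length(V))
  with(params, V + (dt / tau) * ((v_r - V) + (g_b / g_l) * (V_b - V) +
                                   (g_a / g_l) * (V_a - V)))
}

#' One Euler step of an output-layer soma
#'
#' Integrates
#' \eqn{\tau \dot V = (V_R - V) + (g_d/g_l)(V_b - V) + I(t)}
#' where `I` is the teaching current (0 in the forward phase).
#'
#' @param V Somatic voltage vector.
#' @param V_b Dendritic voltage vector.
#' @param I Teaching current vector (see [teaching_current()]).
#' @param params A [neuron_params()] object.
#' @param dt Time step (ms).
#' @return Updated somatic voltage vector.
#' @export
step_output_soma <- function(V, V_b, I = numeric(length(V)),
                             params = neuron_params(), dt = params$dt) {
  stopifnot(length(V_b) == length(V), length(I) == length(V))
  with(params, V + (dt / tau) * ((v_r - V) + (g_d / g_l) * (V_b - V) + I))
}

#' Teaching current at the output layer
#'
#' Conductance-based somatic current
#' \eqn{I_i = g_{E,i}(E_E - V_i) + g_{I,i}(E_I - V_i)}. In the forward phase
#' the current is zero everywhere. In the target phase the unit coding the
#' correct class gets `g_E = 1, g_I = 0` (clamped toward the excitatory
#' reversal, saturating its firing rate) and every other unit gets
#' `g_E = 0, g_I = 1` (clamped toward the inhibitory reversal, silencing it).
#' Under the default `teach_scale = "inverse_leak"` the current is divided
#' by `g_l`, matching the ratio units of the dendritic terms.
#'
#' @param V Output somatic voltage vector.
#' @param target_class Index (1-based) of the correct output unit, or `NULL`.
#' @param phase `"forward"` or `"target"`.
#' @param params A [neuron_params()] object.
#' @return Current vector `I`.
#' @export
teaching_current <- function(V, target_class = NULL,
                             phase = c("forward", "target"),
                             params = neuron_params()) {
  phase <- match.arg(phase)
  n <- length(V)
  if (phase == "forward" || is.null(target_class)) return(numeric(n))
  if (!is.numeric(target_class) || target_class < 1 || target_class > n) {
    stop("target_class out of range", call. = FALSE)
  }
  gE <- numeric(n); gE[target_class] <- 1
  gI <- 1 - gE
  scale <- if (params$teach_scale == "literal") 1 else 1 / params$g_l
  scale * (gE * (params$e_e - V) + gI * (params$e_i - V))
}

#' Instantaneous firing rates
#'
#' Logistic rate function \eqn{\phi(V) = \phi_{max}\,\sigma(V)} with
#' \eqn{\sigma(V) = 1/(1+e^{-V})}; rates lie in `(0, phi_max)` spikes/ms.
#'
#' @param V Somatic voltage vector.
#' @param phi_max Maximum firing rate (spikes/ms).
#' @return Rate vector (spikes/ms).
#' @export
firing_rates <- function(V, phi_max = 0.2) {
  phi_max * sigmoid(V)
}

#' Sample Poisson spikes for one time step
#'
#' Each unit spikes independently with probability `rate * dt` this step
#' (a Bernoulli approximation of the Poisson process, valid while
#' `rate * dt < 1`; at the defaults the maximum is 0.2).
#'
#' @param rates Rate vector (spikes/ms).
#' @param dt Time step (ms).
#' @return Logical spike vector.
#' @export
sample_spikes <- function(rates, dt = 1) {
  if (any(rates < 0)) stop("negative firing rates", call. = FALSE)
  stats::runif(length(rates)) < rates * dt
}
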