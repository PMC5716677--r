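#' Synaptic kernel parameters
#'
#' Time constants of the double-exponential postsynaptic kernel
#' \eqn{\kappa(t) = (e^{-t/\tau_L} - e^{-t/\tau_s})\,\Theta(t)/(\tau_L-\tau_s)},
#' which integrates to 1 so that the time-averaged filtered spike train of a
#' Poisson unit estimates its firing rate (in spikes/ms).
#'
#' @param tau_s Short synaptic time constant (ms).
#' @param tau_l Long synaptic time constant (ms). Must exceed `tau_s`.
#' @return An object of class `kernel_params`.
#' @examples
#' kp <- kernel_params()
#' kernel_value(3, kp)
#' @export
kernel_params <- function(tau_s = 3, tau_l = 10) {
  if (!is.numeric(tau_s) || !is.numeric(tau_l) ||
      tau_s <= 0 || tau_l <= tau_s) {
    stop("invalid kernel parameters: need 0 < tau_s < tau_l", call. = FALSE)
  }
  structure(list(tau_s = tau_s, tau_l = tau_l), class = "kernel_params")
}

#' Neuron and simulation parameters
#'
#' All compartmental conductances and simulation constants in one object.
#' Voltages are dimensionless values on the model's native scale (rest at 0,
#' excitatory reversal +8, inhibitory reversal -8, dendritic initialisation
#' range -6..12). Rates are kept in spikes/ms internally (`phi_max = 0.2`,
#' i.e. 200 Hz) so that filtered spike trains and firing rates live on the
#' same scale; report in Hz by multiplying by 1000.
#'
#' @param g_l Leak conductance.
#' @param g_b Basal dendrite to soma conductance (hidden layers).
#' @param g_a Apical dendrite to soma conductance (hidden layers); 0 gives
#'   total electrotonic segregation, 0.05 strong attenuation, 0.6 weak.
#' @param g_d Dendrite to soma conductance (output layer).
#' @param c_m Membrane capacitance; the membrane time constant is `c_m / g_l`.
#' @param v_r Resting potential.
#' @param phi_max Maximum firing rate in spikes/ms.
#' @param e_e,e_i Excitatory and inhibitory reversal potentials of the
#'   teaching current.
#' @param dt Integration time step (ms); forward Euler requires
#'   `dt <= tau/5` where `tau = c_m/g_l`.
#' @param tau_s,tau_l Synaptic kernel time constants (ms).
#' @param settle Settling time (ms) excluded from phase averages.
#' @param teach_scale `"inverse_leak"` scales the teaching current by
#'   `1/g_l`, putting it on the same ratio scale as the dendritic
#'   conductance terms so that the clamped output unit saturates and the
#'   others are silenced; `"literal"` adds the current unscaled.
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' attenuation_factors(p)
#' @export
neuron_params <- function(g_l = 0.1, g_b = 0.6, g_a = 0, g_d = 0.6,
                          c_m = 1, v_r = 0, phi_max = 0.2,
                          e_e = 8, e_i = -8, dt = 1,
                          tau_s = 3, tau_l = 10, settle = 30,
                          teach_scale = c("inverse_leak", "literal")) {
  teach_scale <- match.arg(teach_scale)
  stopifnot(g_l > 0, g_b >= 0, g_a >= 0, g_d >= 0, c_m > 0,
            phi_max > 0, dt > 0, settle >= 0)
  tau <- c_m / g_l
  if (dt > tau / 5) {
    stop("dt too large for stable Euler integration: need dt <= tau/5",
         call. = FALSE)
  }
  kp <- kernel_params(tau_s = tau_s, tau_l = tau_l)
  structure(
    list(g_l = g_l, g_b = g_b, g_a = g_a, g_d = g_d, c_m = c_m, v_r = v_r,
         phi_max = phi_max, e_e = e_e, e_i = e_i, dt = dt, tau = tau,
         kernel = kp, settle = settle, teach_scale = teach_scale),
    class = "neuron_params"
  )
}

#' Dendritic attenuation factors
#'
#' Steady-state transfer factors from dendrite to soma:
#' `k_d = g_d/(g_l + g_d)` for the output layer and
#' `k_b = g_b/(g_l + g_b + g_a)` for hidden layers. With constant dendritic
#' drive the somatic voltage converges to `k * V_dendrite`.
#'
#' @param params A [neuron_params()] object.
#' @return A list with elements `k_d` and `k_b`.
#' @export
attenuation_factors <- function(params) {
  list(k_d = params$g_d / (params$g_l + params$g_d),
       k_b = params$g_b / (params$g_l + params$g_b + params$g_a))
}

#' Error-signal scaling factors
#'
#' Gradient-descent scaling constants applied with the learning rates:
#' `P0 = 20/phi_max` for hidden layers and `P1 = 20/phi_max^2` for the
#' output layer (rates in spikes/ms, so 100 and 500 at the defaults).
#'
#' @param phi_max Maximum firing rate in spikes/ms.
#' @return A list with elements `P0` and `P1`.
#' @export
error_scaling <- function(phi_max = 0.2) {
  list(P0 = 20 / phi_max, P1 = 20 / phi_max^2)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_prime <- function(x) {
  s <- sigmoid(x)
  s * (1 - s)
}
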