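#' Postsynaptic response kernel
#'
#' Evaluates \eqn{\kappa(t) = (e^{-t/\tau_L} - e^{-t/\tau_s})\Theta(t)/(\tau_L-\tau_s)},
#' the unit-integral double-exponential kernel used to filter presynaptic
#' spike trains into postsynaptic traces.
#'
#' @param t Time since the presynaptic spike (ms); vectorised.
#' @param kp A [kernel_params()] object.
#' @return Kernel weight(s) in 1/ms; 0 for `t < 0`.
#' @export
kernel_value <- function(t, kp = kernel_params()) {
  stopifnot(inherits(kp, "kernel_params"))
  ifelse(t >= 0,
         (exp(-t / kp$tau_l) - exp(-t / kp$tau_s)) / (kp$tau_l - kp$tau_s),
         0)
}

#' Create an empty filtered-trace state
#'
#' The trace is maintained incrementally with two exponential accumulators
#' (one per kernel time constant) rather than by storing spike times; the
#' current trace value is their scaled difference, which equals the direct
#' convolution of the spike raster with [kernel_value()].
#'
#' @param n Number of presynaptic units.
#' @param kp A [kernel_params()] object.
#' @return An object of class `spike_trace` with a `value` field (>= 0).
#' @export
new_trace <- function(n, kp = kernel_params()) {
  structure(list(s_l = numeric(n), s_s = numeric(n), value = numeric(n),
                 kp = kp),
            class = "spike_trace")
}

#' Advance filtered spike trains by one time step
#'
#' Decays both exponential accumulators by `dt` and adds the new spikes.
#' A spike contributes 0 at its own step (the kernel vanishes at t = 0) and
#' the full double-exponential response thereafter.
#'
#' @param trace A `spike_trace` state from [new_trace()].
#' @param spikes Logical (or 0/1) vector of spike events this step.
#' @param dt Time step (ms).
#' @return The updated `spike_trace`.
#' @export
filter_spike_trains <- function(trace, spikes, dt = 1) {
  stopifnot(inherits(trace, "spike_trace"), dt > 0)
  if (length(spikes) != length(trace$s_l)) {
    stop("spike vector length does not match trace state", call. = FALSE)
  }
  sp <- as.numeric(spikes)
  kp <- trace$kp
  trace$s_l <- trace$s_l * exp(-dt / kp$tau_l) + sp
  trace$s_s <- trace$s_s * exp(-dt / kp$tau_s) + sp
  trace$value <- (trace$s_l - trace$s_s) / (kp$tau_l - kp$tau_s)
  trace
}

#' Filter a whole spike raster
#'
#' Runs [filter_spike_trains()] over a raster and returns the trace at every
#' step. Useful for analyses and for validating the incremental filter
#' against direct convolution with the kernel.
#'
#' @param raster steps x units matrix (logical or 0/1) of spikes.
#' @param kp A [kernel_params()] object.
#' @param dt Time step (ms).
#' @return A steps x units matrix of trace values.
#' @export
filter_raster <- function(raster, kp = kernel_params(), dt = 1) {
  raster <- as.matrix(raster)
  tr <- new_trace(ncol(raster), kp)
  out <- matrix(0, nrow(raster), ncol(raster))
  for (t in seq_len(nrow(raster))) {
    tr <- filter_spike_trains(tr, raster[t, ], dt)
    out[t, ] <- tr$value
  }
  out
}
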