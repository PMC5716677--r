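# Pure-R reference trial simulator. Slow, used in tests to validate the
# compiled engine step for step: it composes the exported per-step
# operations and consumes the RNG stream in exactly the same order (input
# uniforms, hidden layers bottom-to-top, output), so under the same seed and
# fixed phase lengths it must reproduce the engine's trial averages.
run_trial_reference <- function(net, input_rates, target_class,
                                steps_forward, steps_target) {
  p <- net$params
  kp <- p$kernel
  settle <- as.integer(round(p$settle / p$dt))
  L <- net$n_hidden
  sizes <- net$sizes
  n <- net$n_classes
  Ylist <- lapply(net$Y, `[[`, "Y")

  tr_in <- new_trace(net$input_dim, kp)
  hV <- lapply(net$hidden, numeric)
  tr_h <- lapply(net$hidden, new_trace, kp = kp)
  oV <- numeric(n)
  tr_o <- new_trace(n, kp)
  phi_o <- numeric(n)

  run_phase <- function(nsteps, phase) {
    sums <- list(v = lapply(c(net$hidden, n), numeric),
                 phi = lapply(c(net$hidden, n), numeric),
                 s = lapply(c(net$input_dim, net$hidden, n), numeric),
                 va = lapply(net$hidden, numeric))
    hist <- lapply(net$hidden, function(m) matrix(0, nsteps, m))
    navg <- 0
    for (t in seq_len(nsteps)) {
      sp_in <- sample_spikes(input_rates, p$dt)
      tr_in <<- filter_spike_trains(tr_in, sp_in, p$dt)
      fb <- if (identical(net$apical_feedback, "rates")) phi_o else tr_o$value
      for (k in seq_len(L)) {
        pre <- if (k == 1) tr_in$value else tr_h[[k - 1]]$value
        vb <- dendrite_voltage(net$W[[k]], pre, net$b[[k]])
        va <- drop(Ylist[[k]] %*% fb)
        hV[[k]] <<- step_hidden_soma(hV[[k]], vb, va, p, p$dt)
        phi <- firing_rates(hV[[k]], p$phi_max)
        sp <- sample_spikes(phi, p$dt)
        tr_h[[k]] <<- filter_spike_trains(tr_h[[k]], sp, p$dt)
        hist[[k]][t, ] <- va
        if (t > settle) {
          sums$v[[k]] <- sums$v[[k]] + hV[[k]]
          sums$phi[[k]] <- sums$phi[[k]] + phi
          sums$s[[k + 1]] <- sums$s[[k + 1]] + tr_h[[k]]$value
          sums$va[[k]] <- sums$va[[k]] + va
        }
      }
      pre_o <- if (L == 0) tr_in$value else tr_h[[L]]$value
      vbo <- dendrite_voltage(net$W[[L + 1]], pre_o, net$b[[L + 1]])
      I <- teaching_current(oV, target_class, phase, p)
      oV <<- step_output_soma(oV, vbo, I, p, p$dt)
      phi_o <<- firing_rates(oV, p$phi_max)
      sp_o <- sample_spikes(phi_o, p$dt)
      tr_o <<- filter_spike_trains(tr_o, sp_o, p$dt)
      if (t > settle) {
        sums$v[[L + 1]] <- sums$v[[L + 1]] + oV
        sums$phi[[L + 1]] <- sums$phi[[L + 1]] + phi_o
        sums$s[[1]] <- sums$s[[1]] + tr_in$value
        sums$s[[L + 2]] <- sums$s[[L + 2]] + tr_o$value
        navg <- navg + 1
      }
    }
    list(v = lapply(sums$v, `/`, navg),
         phi = lapply(sums$phi, `/`, navg),
         s = lapply(sums$s, `/`, navg),
         va = lapply(sums$va, `/`, navg),
         va_hist = hist, steps = nsteps, averaged_steps = navg)
  }

  fwd <- run_phase(steps_forward, "forward")
  tgt <- if (steps_target > 0) run_phase(steps_target, "target") else NULL
  list(forward = name_phase(fwd, net), target = name_phase(tgt, net))
}
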