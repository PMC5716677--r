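# Central-difference gradient of a scalar function of a matrix/vector.
fd_grad <- function(f, W, h = 1e-6) {
  g <- W
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W
    Wp[i] <- W[i] + h
    Wm[i] <- W[i] - h
    g[i] <- (f(Wp) - f(Wm)) / (2 * h)
  }
  g
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}

sig <- function(x) 1 / (1 + exp(-x))

# Deterministic, self-consistent trial record at the rate-model steady state:
# forward averages satisfy Vbar = k * (W x + b) and sbar_hidden = phibar =
# phi_max * sigma(Vbar), so the learning rules' residuals coincide with the
# quantities the finite-difference oracles differentiate.
make_consistent_trial <- function(net, x, phi1_star, dalpha = NULL) {
  p <- net$params
  att <- attenuation_factors(p)
  L <- net$n_hidden
  v <- list(); phi <- list(); s <- list(input = x)
  pre <- x
  for (k in seq_len(L)) {
    key <- paste0("hidden", k)
    v[[key]] <- att$k_b * drop(net$W[[k]] %*% pre + net$b[[k]])
    phi[[key]] <- firing_rates(v[[key]], p$phi_max)
    s[[key]] <- phi[[key]]
    pre <- phi[[key]]
  }
  v$output <- att$k_d * drop(net$W[[L + 1]] %*% pre + net$b[[L + 1]])
  phi$output <- firing_rates(v$output, p$phi_max)
  s$output <- phi$output

  fwd <- list(v = v, phi = phi, s = s)
  tgt <- fwd
  tgt$phi$output <- phi1_star

  plateaus <- NULL
  if (L > 0) {
    plateaus <- lapply(seq_len(L), function(k) {
      d <- if (is.null(dalpha)) numeric(net$hidden[k]) else dalpha[[k]]
      list(alpha_f = rep(0.5, net$hidden[k]),
           alpha_t = 0.5 + d)
    })
    names(plateaus) <- paste0("hidden", seq_len(L))
  }
  structure(list(mode = "train", target_class = 1L, forward = fwd,
                 target = tgt, plateaus = plateaus, input_rates = x,
                 steps = c(forward = 52L, target = 52L)),
            class = "dendrite_trial")
}
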