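#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-epoch training metrics
#'
#' @param x A `dendrite_fit`.
#' @param ... Unused.
#' @return The per-epoch tibble: `epoch`, `test_error`, mean losses and the
#'   Jacobian eigenvalue monitor.
#' @export
tidy.dendrite_fit <- function(x, ...) {
  x$epochs
}

#' One-row summary of a training run
#'
#' @param x A `dendrite_fit`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, epochs, presentations, final test
#'   error, final mean losses and final Jacobian eigenvalue.
#' @export
glance.dendrite_fit <- function(x, ...) {
  last <- if (nrow(x$epochs)) x$epochs[nrow(x$epochs), ] else
    tibble::tibble(test_error = NA_real_, mean_loss_output = NA_real_,
                   jacobian_mu = NA_real_)
  tibble::tibble(
    architecture = paste(x$net$sizes, collapse = "-"),
    n_hidden = x$net$n_hidden,
    feedback = x$net$feedback,
    epochs = x$n_epochs,
    presentations = nrow(x$presentations),
    test_error = last$test_error,
    mean_loss_output = last$mean_loss_output,
    jacobian_mu = last$jacobian_mu
  )
}

#' Tidy a network's layer structure
#'
#' @param x A `dendrite_net`.
#' @param ... Unused.
#' @return A tibble with one row per trainable layer: sizes and weight
#'   summaries.
#' @export
tidy.dendrite_net <- function(x, ...) {
  n_layers <- length(x$W)
  tibble::tibble(
    layer = c(if (x$n_hidden > 0) paste0("hidden", seq_len(x$n_hidden)),
              "output"),
    n_units = vapply(x$W, nrow, integer(1)),
    fan_in = vapply(x$W, ncol, integer(1)),
    w_mean = vapply(x$W, mean, numeric(1)),
    w_sd = vapply(x$W, stats::sd, numeric(1)),
    b_mean = vapply(x$b, mean, numeric(1))
  )
}
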