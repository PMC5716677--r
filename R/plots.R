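#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the learning curve of a fit
#'
#' Test error (when recorded) across epochs.
#'
#' @param object A `dendrite_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dendrite_fit <- function(object, ...) {
  df <- object$epochs
  if (!nrow(df) || all(is.na(df$test_error))) {
    stop("no test evaluations recorded; train with test_data", call. = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$test_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "test error (%)",
                  title = "Classification error across training") +
    ggplot2::theme_minimal()
}

#' Plot the local-vs-backprop update angle
#'
#' Sliding-window mean of the per-presentation angle between the local
#' hidden-layer update and the backpropagation oracle update, with the
#' 90-degree orthogonality line marked: sustained values below 90 mean the
#' local rule points its updates in a direction aligned with explicit
#' backpropagation.
#'
#' @param fit A `dendrite_fit` trained with `track_angle = TRUE`.
#' @param window Sliding-window length (presentations).
#' @return A ggplot.
#' @export
plot_update_angles <- function(fit, window = 100) {
  ang <- fit$presentations$angle
  if (all(is.na(ang))) {
    stop("no angles recorded; train with track_angle = TRUE", call. = FALSE)
  }
  df <- tibble::tibble(presentation = seq_along(ang),
                       angle = sliding_mean(ang, window))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$presentation,
                                   y = .data$angle)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed") +
    ggplot2::labs(x = "image presentation",
                  y = sprintf("angle vs backprop (deg, window %d)", window),
                  title = "Local updates vs backpropagation") +
    ggplot2::theme_minimal()
}

#' Plot hidden/output loss coordination
#'
#' Per-class correlation between hidden and output losses against the
#' shuffled-pairing control.
#'
#' @param records Per-presentation loss records (see [loss_correlation()]).
#' @return A ggplot.
#' @export
plot_loss_coordination <- function(records) {
  lc <- loss_correlation(records)
  long <- dplyr::bind_rows(
    tibble::tibble(label = lc$label, r = lc$r, series = "real"),
    tibble::tibble(label = lc$label, r = lc$r_shuffled, series = "shuffled"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$label), y = .data$r,
                                     colour = .data$series)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "class", y = "Pearson r(L0, L1)",
                  title = "Hidden/output loss coordination") +
    ggplot2::theme_minimal()
}
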