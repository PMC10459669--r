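# broom-style accessors and plots for fitted models

#' Tidy the training history of a fit
#'
#' @param x An `equivs_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `valid_mse`.
#' @export
tidy.equivs_fit <- function(x, ...) {
  as_tibble(x$history)
}

#' One-row summary of a fit
#'
#' @param x An `equivs_fit`.
#' @param ... Unused.
#' @return Tibble with the variant, architecture widths, epoch counts,
#'   parameter count and best validation MSE.
#' @export
glance.equivs_fit <- function(x, ...) {
  tibble(
    variant = x$config$variant,
    hidden_dim = x$config$hidden_dim,
    n_layers = x$config$n_layers,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_valid_mse = x$best_valid_mse,
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}

#' Training-curve plot
#'
#' Train loss and validation MSE per epoch, with the selected checkpoint
#' marked.
#'
#' @param object An `equivs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.equivs_fit <- function(object, ...) {
  hist_long <- object$history |>
    tidyr::pivot_longer(c("train_loss", "valid_mse"),
                        names_to = "series", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed plot
#'
#' @param predictions Output of [predict.equivs_fit()] joined with labels,
#'   i.e. a data frame with `value_logM` and `.pred` columns.
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions) {
  stopifnot(all(c("value_logM", ".pred") %in% names(predictions)))
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$value_logM, y = .data$.pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed (-logM)", y = "predicted (-logM)") +
    ggplot2::theme_minimal()
}
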