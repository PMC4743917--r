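# ggplot2 visualisations for paths and segmentations.

#' Plot a regularization path
#'
#' Refit coefficient trajectories against \eqn{\log \tilde\lambda}, plus the
#' support size as a secondary panel-free annotation (line width encodes
#' selection).
#'
#' @param object An `"ar_path"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ar_path <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log(.data$lambda), y = .data$estimate,
                                  group = .data$term, colour = .data$term)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = expression(log(tilde(lambda))),
                  y = "refit coefficient",
                  title = sprintf("Adaptive ridge path (%s)", object$family)) +
    ggplot2::theme_minimal()
}

#' @export
plot.ar_path <- function(x, ...) print(autoplot.ar_path(x, ...))

#' Plot a segmentation fit
#'
#' The observed signal with the refit piecewise-constant means and dashed
#' vertical lines at the declared breakpoints.
#'
#' @param object An `"ar_segmentation"` or `"dp_segmentation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ar_segmentation <- function(object, ...) {
  d <- tibble::tibble(index = seq_along(object$y), y = object$y,
                      fitted = object$fitted)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.35, size = 0.7) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::labs(x = "position", y = "signal") +
    ggplot2::theme_minimal()
  if (length(object$breakpoints))
    g <- g + ggplot2::geom_vline(xintercept = object$breakpoints + 0.5,
                                 linetype = "dashed", alpha = 0.5)
  g
}

#' @export
autoplot.dp_segmentation <- autoplot.ar_segmentation

#' @export
plot.ar_segmentation <- function(x, ...) print(autoplot.ar_segmentation(x, ...))

#' @export
plot.dp_segmentation <- function(x, ...) print(autoplot.ar_segmentation(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
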