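#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-epoch training trace (loss or free energy) for
#' offline fits and the per-stage accuracy/ECE table for continual fits;
#' `glance()` returns a one-row summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.snn_fit <- function(x, ...) x$loss_trace

#' @rdname tidy.snn_fit
#' @export
tidy.svi_fit <- function(x, ...) x$fe_trace

#' @rdname tidy.snn_fit
#' @export
tidy.continual_fit <- function(x, ...) x$metrics

#' @rdname tidy.snn_fit
#' @export
tidy.calibration_report <- function(x, ...) x$bins

#' @rdname tidy.snn_fit
#' @export
glance.snn_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$loss_trace),
                 final_loss = utils::tail(x$loss_trace$loss, 1),
                 binary = x$binary)
}

#' @rdname tidy.snn_fit
#' @export
glance.svi_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$fe_trace),
                 final_free_energy = utils::tail(x$fe_trace$free_energy, 1),
                 family = x$family, rho = x$cfg$rho)
}

#' @rdname tidy.snn_fit
#' @export
glance.continual_fit <- function(x, ...) {
  final <- dplyr::filter(x$metrics, .data$stage == max(.data$stage))
  tibble::tibble(method = x$method, tasks = max(x$metrics$stage),
                 mean_accuracy = mean(final$accuracy),
                 mean_ece = mean(final$ece))
}

#' @rdname tidy.snn_fit
#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(n = x$n, M = x$M, ece = x$ece,
                 accuracy = x$accuracy %||% NA_real_)
}

#' Training-trace plot
#'
#' @param object An `snn_fit` or `svi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snn_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.snn_fit
#' @export
autoplot.svi_fit <- function(object, ...) {
  ggplot2::ggplot(object$fe_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "variational free energy") +
    ggplot2::theme_minimal()
}

#' Per-task accuracy trajectory of a continual fit
#'
#' @param object A `continual_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.continual_fit <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$stage, y = .data$accuracy,
                               colour = factor(.data$task))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training stage (tasks completed)", y = "test accuracy",
                  colour = "task") +
    ggplot2::theme_minimal()
}
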