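#' Reliability binning of decisions
#'
#' Partitions the confidence axis into `M` half-open bins
#' `((m-1)/M, m/M]` and computes, per bin, the number of decisions falling in
#' it, their average accuracy, and their average confidence. Empty bins are
#' kept in the report with count 0 and `NA` averages; they carry zero weight
#' in the expected calibration error.
#'
#' @param decisions Data frame with numeric `confidence` in (0, 1\] and
#'   logical `correct`.
#' @param M Number of bins (default 10).
#' @return A `calibration_report`: list with `M`, `n`, a tibble `bins`
#'   (`bin`, `lo`, `hi`, `count`, `acc`, `conf`) and the `ece`.
#' @export
reliability_bins <- function(decisions, M = 10L) {
  stopifnot(is.data.frame(decisions), M >= 1L)
  conf <- decisions$confidence
  if (any(conf <= 0 | conf > 1)) {
    stop("confidences must lie in (0, 1]", call. = FALSE)
  }
  correct <- as.logical(decisions$correct)
  idx <- pmin(ceiling(conf * M), M)  # conf = m/M lands in bin m
  bins <- tibble::tibble(
    bin = seq_len(M),
    lo = (seq_len(M) - 1) / M,
    hi = seq_len(M) / M,
    count = vapply(seq_len(M), function(m) sum(idx == m), 0L),
    acc = vapply(seq_len(M), function(m) {
      if (any(idx == m)) mean(correct[idx == m]) else NA_real_
    }, 0),
    conf = vapply(seq_len(M), function(m) {
      if (any(idx == m)) mean(conf[idx == m]) else NA_real_
    }, 0)
  )
  report <- structure(list(M = as.integer(M), n = length(conf), bins = bins),
                      class = "calibration_report")
  report$ece <- ece(report)
  report
}

#' Expected calibration error
#'
#' `ECE = (1/n) * sum_m |B_m| * |conf(B_m) - acc(B_m)|` over occupied bins;
#' always in \[0, 1\].
#'
#' @param report A [reliability_bins()] report.
#' @return Scalar ECE.
#' @export
ece <- function(report) {
  stopifnot(inherits(report, "calibration_report"))
  if (report$n == 0L) stop("empty decision set", call. = FALSE)
  occ <- report$bins$count > 0L
  sum(report$bins$count[occ] *
        abs(report$bins$conf[occ] - report$bins$acc[occ])) / report$n
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report: n=%d, M=%d, ECE=%.4f>\n", x$n, x$M, x$ece))
  occ <- x$bins[x$bins$count > 0L, ]
  print(occ, n = nrow(occ))
  invisible(x)
}

#' Out-of-distribution confidence histogram
#'
#' Counts confidences over the same `((m-1)/M, m/M]` bins used by
#' [reliability_bins()]; bin counts sum to the number of examples.
#'
#' @param confidences Numeric confidences in (0, 1\].
#' @param M Number of bins.
#' @return Tibble with `bin`, `lo`, `hi`, `count`.
#' @export
ood_histogram <- function(confidences, M = 10L) {
  if (any(confidences <= 0 | confidences > 1)) {
    stop("confidences must lie in (0, 1]", call. = FALSE)
  }
  idx <- pmin(ceiling(confidences * M), M)
  tibble::tibble(bin = seq_len(M),
                 lo = (seq_len(M) - 1) / M,
                 hi = seq_len(M) / M,
                 count = vapply(seq_len(M), function(m) sum(idx == m), 0L))
}

#' Score predictions against labels
#'
#' @param pd A [predictive_distribution()].
#' @param labels Zero-based true class labels.
#' @return Tibble with `confidence` and `correct`, ready for
#'   [reliability_bins()].
#' @export
score_predictions <- function(pd, labels) {
  stopifnot(inherits(pd, "predictive_distribution"),
            length(labels) == length(pd$prediction))
  tibble::tibble(confidence = pd$confidence,
                 correct = pd$prediction == as.integer(labels))
}

#' Accuracy, ECE and reliability report in one call
#'
#' @inheritParams score_predictions
#' @param M Number of reliability bins.
#' @return A `calibration_report` with an added `accuracy` element.
#' @export
calibration_summary <- function(pd, labels, M = 10L) {
  scored <- score_predictions(pd, labels)
  report <- reliability_bins(scored, M)
  report$accuracy <- mean(scored$correct)
  report
}

#' Serialize a calibration report to JSON
#'
#' @param report A `calibration_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(report, path) {
  payload <- list(M = report$M, n = report$n, ece = report$ece,
                  accuracy = report$accuracy %||% NA,
                  bins = report$bins)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Reliability diagram
#'
#' Plots per-bin accuracy against the bin midpoints with the identity
#' (perfect-calibration) line; occupied bins only.
#'
#' @param object A `calibration_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_report <- function(object, ...) {
  df <- object$bins[object$bins$count > 0L, ]
  df$mid <- (df$lo + df$hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$acc)) +
    ggplot2::geom_col(width = 1 / object$M, fill = "steelblue",
                      colour = "grey30", alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$conf), shape = 4, size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "confidence", y = "accuracy",
                  title = sprintf("Reliability diagram (ECE = %.3f)", object$ece)) +
    ggplot2::theme_minimal()
}

#' Confidence histogram plot
#'
#' @param hist A tibble from [ood_histogram()].
#' @return A ggplot object.
#' @export
plot_confidence_histogram <- function(hist) {
  hist$mid <- (hist$lo + hist$hi) / 2
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(hist), fill = "darkorange",
                      colour = "grey30", alpha = 0.8) +
    ggplot2::labs(x = "confidence", y = "count",
                  title = "Confidence histogram") +
    ggplot2::theme_minimal()
}
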