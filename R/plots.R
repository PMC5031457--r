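#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training-fraction sweep
#'
#' Mean held-out performance against training fraction, one line per
#' algorithm, with mean +/- SEM ribbons.
#'
#' @param object An `experiment_result` from [run_sweep()].
#' @param metric `"acc"` (class-balanced accuracy, default) or `"f1"`
#'   (macro-F1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, metric = c("acc", "f1"), ...) {
  metric <- match.arg(metric)
  s <- object$summary
  s$mean <- if (metric == "acc") s$acc_mean else s$f1_mean
  s$sem <- if (metric == "acc") s$acc_sem else s$f1_sem
  ggplot2::ggplot(s, ggplot2::aes(x = .data$fraction, y = .data$mean,
                                  colour = .data$algorithm,
                                  fill = .data$algorithm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = "training fraction",
      y = if (metric == "acc") "class-balanced accuracy" else "macro F1") +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A [confusion_matrix()] (counts or percent).
#' @param percent Row-normalize to percent before plotting; default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, percent = TRUE, ...) {
  m <- if (percent) row_normalize(object) else as.matrix(unclass(object))
  df <- as.data.frame(as.table(m))
  names(df) <- c("true", "predicted", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$value)),
                       size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = if (percent) "%" else "n") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Spectrogram-style plot of a recording
#'
#' A quick look at a call's time-frequency content using base
#' [stats::spec.pgram()] over short windows.
#'
#' @param object A [call_recording()].
#' @param window_s Analysis window length in seconds; default 10 ms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.call_recording <- function(object, window_s = 0.01, ...) {
  n_win <- max(32L, 2L * (round(window_s * object$rate) %/% 2L))
  starts <- seq(1L, length(object$samples) - n_win, by = n_win %/% 2L)
  sp <- purrr::map(starts, function(i) {
    seg <- object$samples[i:(i + n_win - 1L)]
    p <- stats::spec.pgram(seg, plot = FALSE, taper = 0.1, detrend = TRUE)
    tibble::tibble(time_s = (i + n_win / 2) / object$rate,
                   freq_hz = p$freq * object$rate,
                   power_db = 10 * log10(p$spec + 1e-12))
  })
  ggplot2::ggplot(dplyr::bind_rows(sp),
                  ggplot2::aes(x = .data$time_s, y = .data$freq_hz / 1000,
                               fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)",
                  title = object$label %||% object$source_id) +
    ggplot2::theme_minimal()
}
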