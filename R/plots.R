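# ggplot2 views of recordings, predictions, CV results and horizon sweeps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recording's kinematics and EMG envelopes
#'
#' @param object An `emg_recording`.
#' @param ... Unused.
#' @return A ggplot: position axes over time (cm) faceted above rectified
#'   EMG channel amplitudes.
#' @export
autoplot.emg_recording <- function(object, ...) {
  pos <- tibble::as_tibble(object$position, .name_repair = ~c("x", "y", "z"))
  pos$time_s <- (seq_len(nrow(pos)) - 1L) / object$fs_pos
  pos_long <- tidyr::pivot_longer(pos, c("x", "y", "z"),
                                  names_to = "axis", values_to = "cm")
  ggplot2::ggplot(pos_long,
                  ggplot2::aes(x = .data$time_s, y = .data$cm,
                               colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      title = sprintf("%s / %s / trial %d", object$metadata$task_id,
                      object$metadata$speed, object$metadata$trial_index),
      x = "time (s)", y = "hand position (cm)", colour = "axis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted against actual trajectories
#'
#' @param actual T x 3 matrix of actual positions (cm).
#' @param predicted T x 3 matrix of predictions.
#' @param fs Sampling rate of the rows (default 20 Hz, the 50 ms feature
#'   step).
#' @return A ggplot with one facet per axis.
#' @export
plot_prediction <- function(actual, predicted, fs = 20) {
  stopifnot(nrow(actual) == nrow(predicted))
  mk <- function(m, which) {
    d <- tibble::as_tibble(m, .name_repair = ~c("x", "y", "z"))
    d$time_s <- (seq_len(nrow(d)) - 1L) / fs
    d$series <- which
    tidyr::pivot_longer(d, c("x", "y", "z"),
                        names_to = "axis", values_to = "cm")
  }
  df <- dplyr::bind_rows(mk(actual, "actual"), mk(predicted, "predicted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$cm,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "position (cm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold decoding performance
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot of per-fold mean CC and NRMSE.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("fold", "cc_mean", "nrmse_mean")],
    c("cc_mean", "nrmse_mean"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold),
                                   y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot performance against the prediction horizon
#'
#' @param object A `horizon_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot of mean CC and NRMSE versus horizon (ms).
#' @export
autoplot.horizon_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("cc_mean", "nrmse_mean"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$horizon_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "prediction horizon (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
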