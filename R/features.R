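# Overlapping-window time-domain EMG features. The seven standard
# Hudgins-style statistics are supported; the default working set is
# {RMS, IEMG}, giving 12 columns for 6 channels.

FEATURE_KINDS <- c("mav", "var", "rms", "wl", "iemg", "ssi", "ssc")

#' Specification of a windowed feature extraction
#'
#' @param feature_set Character subset of `c("mav", "var", "rms", "wl",
#'   "iemg", "ssi", "ssc")`; default `c("rms", "iemg")`, the working
#'   combination for kinematic decoding.
#' @param window_ms Window length in ms, one of 50/100/150/200/250/300
#'   (default 100).
#' @param step_ms Step between window starts in ms (default 50, the same
#'   granularity as the prediction-horizon sweep).
#' @param ssc_threshold Amplitude threshold for slope-sign-change counting
#'   (default 0).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(feature_set = c("rms", "iemg"),
                         window_ms = 100,
                         step_ms = 50,
                         ssc_threshold = 0) {
  feature_set <- tolower(feature_set)
  if (length(feature_set) == 0L || !all(feature_set %in% FEATURE_KINDS)) {
    stop_emg(
      sprintf("`feature_set` must be a non-empty subset of {%s}.",
              paste(FEATURE_KINDS, collapse = ", ")),
      "emgdecode_feature_error"
    )
  }
  if (!is_scalar_number(window_ms) || !is_scalar_number(step_ms) ||
      step_ms <= 0 || window_ms < step_ms) {
    stop_emg("Need window_ms >= step_ms > 0.", "emgdecode_feature_error")
  }
  structure(
    list(feature_set = feature_set, window_ms = window_ms,
         step_ms = step_ms, ssc_threshold = ssc_threshold),
    class = "feature_spec"
  )
}

#' Compute one time-domain feature on a window
#'
#' Definitions (x the window, n its length): MAV = mean(|x|);
#' VAR = sample variance (1/(n-1) normaliser); RMS = sqrt(mean(x^2));
#' WL = sum of absolute successive differences; IEMG = sum(|x|);
#' SSI = sum(x^2); SSC = number of interior samples i with
#' (x_i - x_{i-1})(x_i - x_{i+1}) > threshold.
#'
#' @param x Numeric window (length >= 2; >= 3 for SSC).
#' @param kind One of `"mav"`, `"var"`, `"rms"`, `"wl"`, `"iemg"`,
#'   `"ssi"`, `"ssc"`.
#' @param ssc_threshold Threshold for SSC (default 0).
#' @return A scalar.
#' @export
window_feature <- function(x, kind, ssc_threshold = 0) {
  kind <- tolower(kind)
  if (!kind %in% FEATURE_KINDS) {
    stop_emg(sprintf("Unknown feature kind '%s'.", kind),
             "emgdecode_feature_error")
  }
  min_n <- if (kind == "ssc") 3L else 2L
  assert_numeric_vector(x, "x", min_len = min_n)
  n <- length(x)
  switch(kind,
    mav = mean(abs(x)),
    var = stats::var(x),
    rms = sqrt(mean(x^2)),
    wl = sum(abs(diff(x))),
    iemg = sum(abs(x)),
    ssi = sum(x^2),
    ssc = {
      xm <- x[2:(n - 1L)]
      sum((xm - x[1:(n - 2L)]) * (xm - x[3:n]) > ssc_threshold)
    }
  )
}

#' Overlapping-window index schedule
#'
#' Half-open windows `[k*S + 1, k*S + W]` (1-based, inclusive ends) for
#' `k = 0 .. floor((N - W)/S)`.
#'
#' @param length_samples Series length N.
#' @param window_samples Window length W (<= N).
#' @param step_samples Step S (> 0).
#' @return Tibble with columns `start`, `end` (inclusive sample indices).
#' @export
sliding_windows <- function(length_samples, window_samples, step_samples) {
  if (window_samples > length_samples) {
    stop_emg("Window longer than the series: empty window schedule.",
             "emgdecode_window_error")
  }
  if (step_samples <= 0) {
    stop_emg("`step_samples` must be positive.", "emgdecode_window_error")
  }
  k <- 0:((length_samples - window_samples) %/% step_samples)
  tibble::tibble(start = k * step_samples + 1L,
                 end = k * step_samples + window_samples)
}

#' Build the windowed feature matrix of a processed recording
#'
#' Evaluates every feature in the feature spec on every (window, channel) pair of
#' the EMG envelope. Columns are channel-major, feature-minor
#' (`ch1_rms, ch1_iemg, ch2_rms, ...`); with 6 channels and the default
#' {RMS, IEMG} set this is the 12-column decoder input. Each row is
#' stamped with the window-end time in ms.
#'
#' @param proc A `processed_recording` (or any list with `envelope` and
#'   `fs`).
#' @param spec A [feature_spec()].
#' @return A tibble with `t_ms` (window-end time) and one column per
#'   (channel, feature); attribute `"feature_spec"` carries the spec.
#' @export
build_feature_matrix <- function(proc, spec = feature_spec()) {
  if (!inherits(spec, "feature_spec")) {
    stop_emg("`spec` must be a feature_spec.", "emgdecode_input_error")
  }
  env <- proc$envelope
  fs <- proc$fs
  w <- round(spec$window_ms * fs / 1000)
  s <- round(spec$step_ms * fs / 1000)
  wins <- sliding_windows(nrow(env), w, s)
  n_ch <- ncol(env)
  cols <- list(t_ms = wins$end * 1000 / fs)
  for (ch in seq_len(n_ch)) {
    for (kind in spec$feature_set) {
      vals <- vapply(seq_len(nrow(wins)), function(i) {
        window_feature(env[wins$start[i]:wins$end[i], ch], kind,
                       spec$ssc_threshold)
      }, numeric(1))
      cols[[paste0("ch", ch, "_", kind)]] <- vals
    }
  }
  out <- tibble::as_tibble(cols)
  attr(out, "feature_spec") <- spec
  out
}

#' Compare candidate feature sets by decoding performance
#'
#' Runs an evaluation function over each candidate feature set and ranks
#' the candidates by mean correlation (descending). This reproduces the
#' selection procedure that compares individual time-domain features and
#' then their combinations until performance stops improving.
#'
#' @param candidate_sets List of character vectors (feature sets).
#' @param eval_fn Function taking one feature set, returning a list or
#'   named vector with elements `cc` and `nrmse` (means over folds).
#' @return Tibble with columns `features`, `cc`, `nrmse`, sorted by `cc`
#'   descending.
#' @export
compare_feature_sets <- function(candidate_sets, eval_fn) {
  if (length(candidate_sets) == 0L) {
    stop_emg("`candidate_sets` must be non-empty.", "emgdecode_input_error")
  }
  rows <- purrr::map(candidate_sets, function(fs) {
    res <- eval_fn(fs)
    tibble::tibble(
      features = paste(fs, collapse = "+"),
      cc = as.numeric(res[["cc"]]),
      nrmse = as.numeric(res[["nrmse"]])
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$cc))
}
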