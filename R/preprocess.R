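# Signal conditioning: detrend, despike, rectify, linear envelope,
# kinematic resampling. Filters are designed with signal::butter and run
# through signal::filter (direct-form difference equation); the zero-phase
# wrapper handles edge padding by reflection.

#' Remove DC offset and linear trend
#'
#' Subtracts the least-squares straight line from a series, the usual
#' first step of EMG conditioning (drift and DC offset removal).
#'
#' @param x Numeric vector, length >= 2.
#' @return Detrended vector with (numerically) zero mean and zero
#'   correlation with time.
#' @export
remove_dc <- function(x) {
  assert_numeric_vector(x, "x", min_len = 2L)
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - mean(x) - slope * tc
}

#' Median-filter spike removal
#'
#' Sliding-window median with odd kernel; edges are handled by reflecting
#' the series so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param kernel Odd window length in samples (default 5, i.e. 5 ms at
#'   1 kHz).
#' @return Filtered vector, same length as `x`.
#' @export
despike <- function(x, kernel = 5L) {
  assert_numeric_vector(x, "x")
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) {
    stop_emg("`kernel` must be an odd integer >= 3.", "emgdecode_kernel_error")
  }
  h <- kernel %/% 2L
  n <- length(x)
  if (n == 1L) return(x)
  pad_l <- x[pmin(1L + (h:1), n)]
  pad_r <- x[pmax(n - (1:h), 1L)]
  padded <- c(pad_l, x, pad_r)
  out <- stats::runmed(padded, kernel, endrule = "keep")
  out[(h + 1L):(h + n)]
}

#' Full-wave rectification
#'
#' @param x Numeric vector or matrix.
#' @return Element-wise absolute value.
#' @export
rectify <- function(x) abs(x)

# Run the b/a difference equation with the filter state pre-loaded to the
# steady state of the series' first value, so a constant level passes
# through with no start-up transient (essential for narrow low-pass
# filters whose transients outlast any affordable padding).
filter_settled <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], length(b) - 1L),
                            init.y = rep(x[1L] * dc, length(a) - 1L)))
}

# Run b/a difference equation forward and backward over a
# reflection-padded copy of the series (settled initial state at both
# ends); trims back to original length.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  npad <- 3L * max(length(a), length(b)) * 4L
  if (length(a) > 1L) {
    # pad past the slowest pole's settling time so any residual start-up
    # transient dies inside the padding
    r <- max(Mod(polyroot(rev(a))))
    if (is.finite(r) && r > 0 && r < 1) {
      npad <- max(npad, as.integer(ceiling(log(1e-7) / log(r))))
    }
  }
  npad <- min(npad, n - 1L)
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad, by = -1L)]
  y <- c(pre, x, post)
  y <- filter_settled(b, a, y)
  y <- rev(filter_settled(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Linear envelope (2 Hz low-pass)
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (zero-phase, so peaks are not delayed), the standard "linear envelope"
#' smoother for rectified EMG. DC gain is 1.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz; must exceed twice the cutoff.
#' @param cutoff_hz Cutoff frequency (default 2 Hz).
#' @param causal If `TRUE`, apply a single forward pass instead of the
#'   zero-phase double pass (for causal/realtime-style experiments).
#' @return Filtered vector, same length as `x`.
#' @export
linear_envelope <- function(x, fs, cutoff_hz = 2, causal = FALSE) {
  assert_numeric_vector(x, "x", min_len = 2L)
  if (fs <= 2 * cutoff_hz) {
    stop_emg("`fs` must exceed twice the cutoff frequency.",
             "emgdecode_fs_error")
  }
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  if (causal) {
    as.numeric(signal::filter(bf$b, bf$a, x))
  } else {
    zero_phase_filter(bf$b, bf$a, x)
  }
}

#' Resample a position series onto a finer uniform grid
#'
#' Per-axis linear interpolation of the 60 Hz kinematic samples onto the
#' 1 kHz EMG clock over their common time span; the original samples are
#' reproduced exactly at their own time stamps. Interpolation corners are
#' removed by the subsequent 2 Hz low-pass in the pipeline.
#'
#' @param position M x 3 matrix (cm).
#' @param fs_in Input rate, Hz (default 60).
#' @param fs_out Output rate, Hz (default 1000).
#' @return N x 3 matrix on the `fs_out` grid.
#' @export
resample_position <- function(position, fs_in = 60, fs_out = 1000) {
  position <- as.matrix(position)
  if (nrow(position) < 2L) {
    stop_emg("`position` needs at least 2 samples.", "emgdecode_input_error")
  }
  t_in <- (seq_len(nrow(position)) - 1L) / fs_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  vapply(seq_len(ncol(position)), function(a) {
    stats::approx(t_in, position[, a], xout = t_out)$y
  }, numeric(length(t_out)))
}

#' Preprocess a recording into envelopes and 1 kHz kinematics
#'
#' Per EMG channel: linear detrend, median despiking, full-wave
#' rectification, and 2 Hz zero-phase Butterworth low-pass (the linear
#' envelope), clipped at zero. Position: linear resampling to 1 kHz
#' followed by the same 2 Hz low-pass per axis. Envelope and position are
#' truncated to a common length.
#'
#' @param rec An `emg_recording`.
#' @param median_kernel Despiking kernel in samples (odd, default 5).
#' @param causal Use causal single-pass filtering (default `FALSE`,
#'   zero-phase offline filtering).
#' @return An object of class `processed_recording` with `envelope`
#'   (N x 6, non-negative), `position_1k` (N x 3, cm), `fs` (1000) and the
#'   recording's `metadata`.
#' @export
preprocess_recording <- function(rec, median_kernel = 5L, causal = FALSE) {
  if (!inherits(rec, "emg_recording")) {
    stop_emg("`rec` must be an emg_recording.", "emgdecode_input_error")
  }
  env <- apply(rec$emg, 2, function(ch) {
    x <- remove_dc(ch)
    x <- despike(x, median_kernel)
    x <- rectify(x)
    pmax(linear_envelope(x, rec$fs_emg, causal = causal), 0)
  })
  pos <- resample_position(rec$position, rec$fs_pos, rec$fs_emg)
  pos <- apply(pos, 2, linear_envelope, fs = rec$fs_emg, causal = causal)
  n <- min(nrow(env), nrow(pos))
  structure(
    list(
      envelope = env[seq_len(n), , drop = FALSE],
      position_1k = pos[seq_len(n), , drop = FALSE],
      fs = rec$fs_emg,
      metadata = rec$metadata
    ),
    class = "processed_recording"
  )
}

#' @export
print.processed_recording <- function(x, ...) {
  cat(sprintf(
    "<processed_recording> %d samples @%g Hz: 6 envelope channels + 3 position axes\n",
    nrow(x$envelope), x$fs
  ))
  invisible(x)
}
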