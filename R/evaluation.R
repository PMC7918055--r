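# Strict-prediction evaluation: cycle segmentation, horizon alignment
# (features at t -> position at t + horizon), NRMSE / Pearson CC metrics,
# five-fold cross-validation over cycles, condition comparison by
# two-sample t-test, and the prediction-horizon sweep.

#' Normalized root-mean-square error
#'
#' RMSE between actual and predicted series divided by the range of the
#' actual series, making errors comparable across axes and scales.
#'
#' @param y Actual series (its range is the normalizer).
#' @param y_hat Predicted series, same length.
#' @return Non-negative scalar; 0 iff the series are identical.
#' @export
nrmse <- function(y, y_hat) {
  assert_numeric_vector(y, "y", min_len = 2L)
  if (length(y) != length(y_hat)) {
    stop_emg("`y` and `y_hat` must have equal length.", "emgdecode_dim_error")
  }
  rng <- max(y) - min(y)
  if (rng <= 0) {
    stop_emg("NRMSE undefined: actual series is constant.",
             "emgdecode_metric_error")
  }
  sqrt(mean((y - y_hat)^2)) / rng
}

#' Pearson correlation coefficient
#'
#' @param y,y_hat Numeric series of equal length, both non-constant.
#' @return Correlation in \[-1, 1\]; invariant under positive affine maps
#'   of either argument.
#' @export
cc <- function(y, y_hat) {
  assert_numeric_vector(y, "y", min_len = 2L)
  if (length(y) != length(y_hat)) {
    stop_emg("`y` and `y_hat` must have equal length.", "emgdecode_dim_error")
  }
  yc <- y - mean(y)
  hc <- y_hat - mean(y_hat)
  denom <- sqrt(sum(yc^2) * sum(hc^2))
  if (denom <= 0) {
    stop_emg("CC undefined: a series has zero variance.",
             "emgdecode_metric_error")
  }
  sum(yc * hc) / denom
}

#' Assemble a per-condition performance report row
#'
#' Means are the arithmetic average of the three per-axis values, the
#' aggregation used for the summary columns of decoding performance
#' tables.
#'
#' @param cc Length-3 numeric: per-axis correlation (x, y, z).
#' @param nrmse Length-3 numeric: per-axis NRMSE.
#' @param ... Optional metadata columns (task, speed, fold, ...).
#' @return One-row tibble with `cc_x/y/z`, `cc_mean`, `nrmse_x/y/z`,
#'   `nrmse_mean`, plus metadata.
#' @export
performance_report <- function(cc, nrmse, ...) {
  stopifnot(length(cc) == 3L, length(nrmse) == 3L)
  tibble::tibble(
    ...,
    cc_x = cc[1], cc_y = cc[2], cc_z = cc[3], cc_mean = mean(cc),
    nrmse_x = nrmse[1], nrmse_y = nrmse[2], nrmse_z = nrmse[3],
    nrmse_mean = mean(nrmse)
  )
}

#' Segment a processed recording into per-cycle analysis windows
#'
#' Cuts one fixed-length segment per movement cycle: 7 s for quick
#' motion, 9 s for slow, starting `margin_s` before the cycle onset so
#' each segment includes preparation before the movement and rest after
#' it. Segments are clipped to the recording (with a warning when
#' truncated).
#'
#' @param proc A `processed_recording`.
#' @param segment_s Segment length in seconds; default 7 (quick) or 9
#'   (slow) from the recording's speed label.
#' @param margin_s Preparation margin before each cycle onset (default
#'   0.5 s).
#' @return List of segments, each a list with `envelope`, `position_1k`,
#'   `fs`, and `metadata` (including `cycle`).
#' @export
segment_cycles <- function(proc, segment_s = NULL, margin_s = 0.5) {
  md <- proc$metadata
  if (is.null(md$cycle_onsets_s)) {
    stop_emg("Recording metadata lacks cycle onsets.", "emgdecode_input_error")
  }
  if (is.null(segment_s)) {
    segment_s <- switch(md$speed, quick = 7, slow = 9)
    if (is.null(segment_s)) {
      stop_emg("Unknown speed label; give `segment_s` explicitly.",
               "emgdecode_speed_error")
    }
  }
  n <- nrow(proc$envelope)
  fs <- proc$fs
  len <- round(segment_s * fs)
  lapply(seq_along(md$cycle_onsets_s), function(ci) {
    start <- max(1L, round((md$cycle_onsets_s[ci] - margin_s) * fs) + 1L)
    end <- start + len - 1L
    if (end > n) {
      warning(sprintf("Segment %d truncated at the end of the recording.", ci))
      end <- n
    }
    idx <- start:end
    list(
      envelope = proc$envelope[idx, , drop = FALSE],
      position_1k = proc$position_1k[idx, , drop = FALSE],
      fs = fs,
      metadata = c(md[c("task_id", "speed", "trial_index")],
                   list(cycle = ci, start_sample = start))
    )
  })
}

#' Align a feature matrix with future positions
#'
#' Builds the strict prediction dataset: the feature row whose window
#' ends at time `t` is paired with the position at `t + horizon_ms`.
#' Rows whose target time falls beyond the recording are dropped.
#'
#' @param features Feature tibble from [build_feature_matrix()] (must
#'   contain `t_ms`).
#' @param position_1k N x 3 position matrix at `fs` Hz.
#' @param horizon_ms Non-negative prediction horizon in ms (0 means
#'   aligned in time; the decoding analysis sweeps 50-300 ms).
#' @param fs Position sampling rate (default 1000).
#' @return List of class `aligned_dataset` with `X` (feature matrix),
#'   `Y` (target positions), `t_ms`, and `horizon_ms`.
#' @export
align_for_horizon <- function(features, position_1k, horizon_ms, fs = 1000) {
  if (!is_scalar_number(horizon_ms) || horizon_ms < 0) {
    stop_emg("`horizon_ms` must be a non-negative number.",
             "emgdecode_horizon_error")
  }
  t_ms <- features$t_ms
  target_idx <- round((t_ms + horizon_ms) * fs / 1000)
  keep <- target_idx >= 1L & target_idx <= nrow(position_1k)
  if (!any(keep)) {
    stop_emg("Horizon beyond the recording for every feature row.",
             "emgdecode_horizon_error")
  }
  X <- as.matrix(features[keep, setdiff(names(features), "t_ms"),
                          drop = FALSE])
  structure(
    list(
      X = X,
      Y = position_1k[target_idx[keep], , drop = FALSE],
      t_ms = t_ms[keep],
      horizon_ms = horizon_ms
    ),
    class = "aligned_dataset"
  )
}

#' Evaluate a fitted model on held-out segments
#'
#' Runs the network over each test segment (recurrent state reset per
#' segment), computes per-axis CC and NRMSE on the denormalized
#' predictions, and averages across segments (or pools all samples with
#' `pooled = TRUE`).
#'
#' @param model A fitted `rfnn`.
#' @param test_sets List of `aligned_dataset`s (or a single one).
#' @param pooled Concatenate segments before computing metrics instead of
#'   averaging per-segment metrics (default `FALSE`).
#' @param ... Metadata columns passed to [performance_report()].
#' @return One-row performance tibble.
#' @export
evaluate_fold <- function(model, test_sets, pooled = FALSE, ...) {
  if (inherits(test_sets, "aligned_dataset")) test_sets <- list(test_sets)
  if (length(test_sets) == 0L) {
    stop_emg("Empty test set.", "emgdecode_input_error")
  }
  preds <- lapply(test_sets, function(d) forward_sequence(model, d$X))
  # a collapsed (constant) prediction carries no association: score CC 0
  # rather than aborting the whole fold
  cc_safe <- function(y, p) if (stats::var(p) <= 0) 0 else cc(y, p)
  if (pooled) {
    Y <- do.call(rbind, lapply(test_sets, `[[`, "Y"))
    P <- do.call(rbind, preds)
    cc_axes <- vapply(1:3, function(a) cc_safe(Y[, a], P[, a]), numeric(1))
    nr_axes <- vapply(1:3, function(a) nrmse(Y[, a], P[, a]), numeric(1))
  } else {
    per_seg <- lapply(seq_along(test_sets), function(i) {
      Y <- test_sets[[i]]$Y
      P <- preds[[i]]
      list(
        cc = vapply(1:3, function(a) cc_safe(Y[, a], P[, a]), numeric(1)),
        nrmse = vapply(1:3, function(a) nrmse(Y[, a], P[, a]), numeric(1))
      )
    })
    cc_axes <- rowMeans(vapply(per_seg, `[[`, numeric(3), "cc"))
    nr_axes <- rowMeans(vapply(per_seg, `[[`, numeric(3), "nrmse"))
  }
  performance_report(cc_axes, nr_axes, ...)
}

# Seeded partition of n cycles into `folds` near-equal folds.
make_cv_plan <- function(n, folds = 5L, seed = 1L) {
  with_seed_(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Cross-validate decoding over cycle segments
#'
#' Randomly partitions the cycles into folds (seeded; 45 cycles give five
#' folds of 9), trains the network on the segments of the remaining
#' folds and evaluates on the held-out fold, resetting the recurrent
#' state at every segment boundary.
#'
#' @param segments List of segments from [segment_cycles()] (pooled
#'   across trials of one condition).
#' @param fspec A [feature_spec()].
#' @param cfg An [rfnn_config()].
#' @param horizon_ms Prediction horizon in ms.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param pooled Pool test samples across segments when computing fold
#'   metrics (default `FALSE`: average per-segment metrics).
#' @return A tibble of class `cv_result`, one row per fold, with the
#'   fold-mean row available via [glance()].
#' @export
cross_validate <- function(segments, fspec = feature_spec(),
                           cfg = rfnn_config(), horizon_ms = 250,
                           folds = 5L, seed = 1L, pooled = FALSE) {
  if (length(segments) < folds) {
    stop_emg(sprintf("Need at least %d segments for %d-fold CV.",
                     folds, folds),
             "emgdecode_input_error")
  }
  datasets <- lapply(segments, function(seg) {
    feats <- build_feature_matrix(seg, fspec)
    align_for_horizon(feats, seg$position_1k, horizon_ms, seg$fs)
  })
  plan <- make_cv_plan(length(segments), folds, seed)
  rows <- lapply(seq_len(folds), function(f) {
    train <- datasets[plan != f]
    test <- datasets[plan == f]
    model <- rfnn_fit(lapply(train, `[[`, "X"),
                      lapply(train, `[[`, "Y"), cfg)
    evaluate_fold(model, test, pooled = pooled, fold = f)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_result", class(out))
  attr(out, "horizon_ms") <- horizon_ms
  attr(out, "cv_plan") <- plan
  out
}

#' Fold-mean summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble of metric means across folds.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(x),
                   dplyr::across(dplyr::starts_with(c("cc_", "nrmse_")),
                                 mean))
}

#' Compare two conditions with a two-sample t-test
#'
#' Pooled-variance two-sample t-test (Welch optional) on a chosen metric
#' across folds or subjects, as used to compare task types and movement
#' speeds.
#'
#' @param reports_a,reports_b Performance tibbles (>= 2 rows each) or
#'   numeric vectors.
#' @param metric Column to compare when tibbles are given (default
#'   `"cc_mean"`).
#' @param welch Use the Welch (unequal-variance) test (default `FALSE`).
#' @return Tibble with `t`, `p_value`, `df`, and the group means.
#' @export
compare_conditions <- function(reports_a, reports_b, metric = "cc_mean",
                               welch = FALSE) {
  pull_metric <- function(r) {
    if (is.numeric(r)) as.numeric(r) else r[[metric]]
  }
  a <- pull_metric(reports_a)
  b <- pull_metric(reports_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_emg("Need at least two values per condition.",
             "emgdecode_input_error")
  }
  if (var(a) + var(b) <= 0) {
    stop_emg("Degenerate (zero) variance in both groups.",
             "emgdecode_metric_error")
  }
  ht <- t.test(a, b, var.equal = !welch)
  tibble::tibble(
    t = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    mean_a = mean(a),
    mean_b = mean(b)
  )
}

#' Sweep the prediction horizon
#'
#' Cross-validates the full decoding pipeline at each horizon and tables
#' mean CC and NRMSE against the horizon, the analysis that locates where
#' performance starts to decline as the prediction time outruns the
#' electromechanical lead.
#'
#' @inheritParams cross_validate
#' @param horizons Horizons in ms (default `seq(50, 300, by = 50)`).
#' @return Tibble of class `horizon_sweep`: `horizon_ms`, `cc_mean`,
#'   `nrmse_mean` (means over folds).
#' @export
horizon_sweep <- function(segments, fspec = feature_spec(),
                          cfg = rfnn_config(),
                          horizons = seq(50, 300, by = 50),
                          folds = 5L, seed = 1L) {
  rows <- lapply(horizons, function(h) {
    cv <- cross_validate(segments, fspec, cfg, horizon_ms = h,
                         folds = folds, seed = seed)
    g <- glance(cv)
    tibble::tibble(horizon_ms = h, cc_mean = g$cc_mean,
                   nrmse_mean = g$nrmse_mean)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("horizon_sweep", class(out))
  out
}
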