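#' Task profile for synthetic trajectory generation
#'
#' Describes one manipulation task archetype: an ordered set of 3-D
#' waypoints inside an axis-aligned workspace box, cycle durations for the
#' quick and slow speed conditions, the break between cycles, and the
#' number of cycles per trial.
#'
#' Two built-in archetypes are provided. `"Task_1"` emulates a pick-and-pour
#' movement inside a 10 x 45 x 50 cm workspace; `"Task_2"` an obstacle-path
#' manipulation inside 20 x 30 x 20 cm. Both default waypoint sequences are
#' closed loops (last waypoint equals the first) so consecutive cycles are
#' continuous and inter-cycle rest happens at the start point.
#'
#' @param task_id `"Task_1"` or `"Task_2"` for a built-in profile.
#' @param waypoints Optional numeric matrix (rows = ordered waypoints,
#'   3 columns, cm) overriding the built-in ones.
#' @param workspace_extent Length-3 numeric, the axis-aligned box (cm).
#' @param cycle_duration_s Named list/vector with elements `quick` and
#'   `slow`, seconds per cycle. Defaults: quick 3 s, slow 5 s.
#' @param break_s Rest between cycles, seconds (default 3).
#' @param cycles_per_trial Number of cycles in one trial (default 5).
#'
#' @return An object of class `task_profile`.
#' @export
task_profile <- function(task_id = c("Task_1", "Task_2"),
                         waypoints = NULL,
                         workspace_extent = NULL,
                         cycle_duration_s = c(quick = 3, slow = 5),
                         break_s = 3,
                         cycles_per_trial = 5L) {
  task_id <- match.arg(task_id)
  if (is.null(workspace_extent)) {
    workspace_extent <- switch(task_id,
      Task_1 = c(10, 45, 50),
      Task_2 = c(20, 30, 20)
    )
  }
  if (is.null(waypoints)) {
    # Fractions of the workspace box; closed loops with out-and-back
    # structure so the path exercises all three axes.
    frac <- switch(task_id,
      Task_1 = rbind( # reach out, lift/pour, set down, return
        c(0.20, 0.10, 0.10),
        c(0.80, 0.45, 0.20),
        c(0.60, 0.80, 0.85),
        c(0.35, 0.60, 0.55),
        c(0.75, 0.30, 0.75),
        c(0.20, 0.10, 0.10)
      ),
      Task_2 = rbind( # weave around obstacles
        c(0.10, 0.15, 0.20),
        c(0.40, 0.70, 0.60),
        c(0.70, 0.25, 0.85),
        c(0.90, 0.80, 0.40),
        c(0.55, 0.50, 0.15),
        c(0.25, 0.85, 0.70),
        c(0.10, 0.15, 0.20)
      )
    )
    waypoints <- sweep(frac, 2, workspace_extent, `*`)
  }
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2L || ncol(waypoints) != 3L) {
    stop_emg("`waypoints` must be a matrix with >= 2 rows and 3 columns.",
             "emgdecode_input_error")
  }
  if (any(waypoints < 0) ||
      any(sweep(waypoints, 2, workspace_extent, `>`))) {
    stop_emg("All waypoints must lie within the workspace box.",
             "emgdecode_input_error")
  }
  cd <- as.list(cycle_duration_s)
  if (!all(c("quick", "slow") %in% names(cd)) ||
      cd$quick >= cd$slow) {
    stop_emg("`cycle_duration_s` needs quick < slow durations.",
             "emgdecode_input_error")
  }
  structure(
    list(
      task_id = task_id,
      waypoints = waypoints,
      workspace_extent = as.numeric(workspace_extent),
      cycle_duration_s = lapply(cd, as.numeric),
      break_s = as.numeric(break_s),
      cycles_per_trial = as.integer(cycles_per_trial)
    ),
    class = "task_profile"
  )
}

#' Muscle-synergy model linking kinematics to EMG amplitude
#'
#' Defines how synthetic EMG channel envelopes are driven by the hand's
#' movement. Each channel's activation is a baseline plus a non-negative
#' mixture of four kinematic drivers (the rectified per-axis velocities
#' and the overall speed), advanced in time by the electromechanical lead:
#' muscle electrical activity precedes mechanical motion by 50-100 ms, and
#' the generator reproduces that lead so ahead-of-time decoding is possible.
#'
#' @param mapping_matrix 6 x 4 non-negative gains (channel x driver). The
#'   default gives each channel a distinct driver mixture so six channels
#'   are jointly informative about three axes.
#' @param electromechanical_lead_ms Lead of activation over motion, must
#'   lie in \[50, 100\] ms. Default 75 ms.
#' @param carrier_band_hz Passband (Hz) of the broadband EMG carrier;
#'   must lie inside (0, 500) (Nyquist at 1 kHz sampling).
#' @param baseline_amplitude Resting activation level (arbitrary units).
#' @param noise_sd Additive sensor-noise standard deviation.
#' @param seed Integer seed for the carrier and noise.
#'
#' @return An object of class `synergy_model`.
#' @export
synergy_model <- function(mapping_matrix = NULL,
                          electromechanical_lead_ms = 75,
                          carrier_band_hz = c(20, 450),
                          baseline_amplitude = 0.2,
                          noise_sd = 0.05,
                          seed = 1L) {
  if (is.null(mapping_matrix)) {
    mapping_matrix <- 0.02 * rbind(
      c(1.0, 0.0, 0.0, 0.3),
      c(0.0, 1.0, 0.0, 0.3),
      c(0.0, 0.0, 1.0, 0.3),
      c(0.7, 0.7, 0.0, 0.2),
      c(0.0, 0.7, 0.7, 0.2),
      c(0.7, 0.0, 0.7, 0.2)
    )
  }
  mapping_matrix <- as.matrix(mapping_matrix)
  if (nrow(mapping_matrix) != 6L) {
    stop_emg("`mapping_matrix` must have 6 rows (channels).",
             "emgdecode_input_error")
  }
  if (any(rowSums(abs(mapping_matrix)) == 0)) {
    stop_emg("Every channel needs at least one nonzero mapping gain.",
             "emgdecode_input_error")
  }
  if (electromechanical_lead_ms < 50 || electromechanical_lead_ms > 100) {
    stop_emg("`electromechanical_lead_ms` must lie in [50, 100] ms.",
             "emgdecode_lead_error")
  }
  if (carrier_band_hz[1] <= 0 || carrier_band_hz[2] >= 500 ||
      carrier_band_hz[1] >= carrier_band_hz[2]) {
    stop_emg("`carrier_band_hz` must be an increasing pair inside (0, 500).",
             "emgdecode_input_error")
  }
  structure(
    list(
      mapping_matrix = mapping_matrix,
      electromechanical_lead_ms = as.numeric(electromechanical_lead_ms),
      carrier_band_hz = as.numeric(carrier_band_hz),
      baseline_amplitude = as.numeric(baseline_amplitude),
      noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed)
    ),
    class = "synergy_model"
  )
}

# Minimum-jerk interpolation between two points: s(tau) with zero velocity
# and acceleration at both ends.
min_jerk_s <- function(tau) {
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' Generate one trial's 3-D hand trajectory
#'
#' Synthesises a smooth cyclic trajectory through the profile's waypoints:
#' each cycle is a chain of minimum-jerk segments (segment durations
#' proportional to inter-waypoint distance), cycles are separated by
#' `break_s` seconds of rest, and a small seeded Gaussian perturbation of
#' the interior waypoints (clamped at 2% of the workspace extent) makes
#' cycles similar but not identical repetitions.
#'
#' @param profile A [task_profile()].
#' @param speed `"quick"` or `"slow"`.
#' @param seed Integer seed for the waypoint jitter.
#' @param jitter_frac Std. dev. of waypoint jitter as a fraction of the
#'   workspace extent (default 0.01, clamped at 0.02); 0 disables jitter.
#' @param fs Position sampling rate, Hz (default 60).
#' @param lead_in_s Rest at the start point before the first cycle
#'   (default 2 s: the preparation time preceding the movement).
#' @param tail_s Rest after the last cycle (default 6 s). With the
#'   defaults a quick trial lasts 35 s and a slow one 45 s, matching the
#'   cycles-plus-preparation-plus-rest structure of real trials; set both
#'   to 0 for the bare cycles-and-breaks duration (27 s / 37 s).
#'
#' @return A list with `position` (M x 3 matrix, cm), `time_s` (length M),
#'   `fs`, and `cycle_onsets_s`.
#' @export
generate_trajectory <- function(profile, speed, seed = 1L,
                                jitter_frac = 0.01, fs = 60,
                                lead_in_s = 2, tail_s = 6) {
  if (!inherits(profile, "task_profile")) {
    stop_emg("`profile` must be a task_profile.", "emgdecode_input_error")
  }
  if (!is.character(speed) || length(speed) != 1L ||
      !speed %in% c("quick", "slow")) {
    stop_emg(sprintf("Unknown speed label %s; use 'quick' or 'slow'.",
                     deparse(speed)),
             "emgdecode_speed_error")
  }
  cyc_dur <- profile$cycle_duration_s[[speed]]
  n_cyc <- profile$cycles_per_trial
  total_dur <- lead_in_s + n_cyc * cyc_dur + (n_cyc - 1L) * profile$break_s +
    tail_s
  time_s <- seq(0, total_dur, by = 1 / fs)
  wp0 <- profile$waypoints
  extent <- profile$workspace_extent
  n_wp <- nrow(wp0)

  jitters <- with_seed_(seed, {
    lapply(seq_len(n_cyc), function(c) {
      j <- matrix(stats::rnorm(n_wp * 3L, sd = jitter_frac), n_wp, 3L)
      pmax(pmin(j, 0.02), -0.02)
    })
  })

  cycle_onsets_s <- lead_in_s +
    (seq_len(n_cyc) - 1L) * (cyc_dur + profile$break_s)
  pos <- matrix(NA_real_, length(time_s), 3L)
  last_pos <- wp0[1L, ]

  for (c in seq_len(n_cyc)) {
    wp <- wp0
    if (jitter_frac > 0 && n_wp > 2L) {
      idx <- 2:(n_wp - 1L) # endpoints fixed so cycles stay continuous
      wp[idx, ] <- wp[idx, ] + sweep(jitters[[c]][idx, , drop = FALSE],
                                     2, extent, `*`)
      wp <- pmax(pmin(wp, matrix(extent, n_wp, 3L, byrow = TRUE)), 0)
    }
    seg_len <- sqrt(rowSums((wp[-1L, , drop = FALSE] -
                             wp[-n_wp, , drop = FALSE])^2))
    if (all(seg_len == 0)) seg_len <- rep(1, n_wp - 1L)
    seg_dur <- cyc_dur * seg_len / sum(seg_len)
    seg_end <- cycle_onsets_s[c] + cumsum(seg_dur)
    seg_start <- c(cycle_onsets_s[c], head(seg_end, -1L))

    in_cycle <- which(time_s >= cycle_onsets_s[c] &
                      time_s <= cycle_onsets_s[c] + cyc_dur)
    for (ti in in_cycle) {
      t <- time_s[ti]
      s <- min(max(findInterval(t, seg_start), 1L), n_wp - 1L)
      tau <- if (seg_dur[s] > 0) (t - seg_start[s]) / seg_dur[s] else 1
      tau <- min(max(tau, 0), 1)
      pos[ti, ] <- wp[s, ] + (wp[s + 1L, ] - wp[s, ]) * min_jerk_s(tau)
    }
    last_pos <- wp[n_wp, ]
    # rest: hold the cycle's end position (the start point for closed paths)
    after <- which(time_s > cycle_onsets_s[c] + cyc_dur)
    if (length(after)) pos[after, ] <- matrix(last_pos, length(after), 3L,
                                              byrow = TRUE)
  }
  unfilled <- is.na(pos[, 1L])
  if (any(unfilled)) {
    pos[unfilled, ] <- matrix(wp0[1L, ], sum(unfilled), 3L, byrow = TRUE)
  }
  list(position = pos, time_s = time_s, fs = fs,
       cycle_onsets_s = cycle_onsets_s)
}

# Zero-phase band-pass used for the synthetic EMG carrier.
bandpass_noise <- function(n, band_hz, fs) {
  bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  x <- stats::rnorm(n)
  zero_phase_filter(bf$b, bf$a, x)
}

#' Synthesize multi-channel surface EMG from a trajectory
#'
#' Per channel, a deterministic activation
#' `a_c(t) = baseline + sum_k mapping[c, k] * driver_k(t + lead)`
#' amplitude-modulates a band-limited Gaussian carrier (normalized to unit
#' mean absolute value, so the linear envelope of the output tracks the
#' activation), and sensor noise is added. The drivers are the rectified
#' per-axis velocities and the overall speed of the (upsampled) trajectory,
#' advanced by the electromechanical lead so the EMG leads the motion.
#'
#' @param trajectory Output of [generate_trajectory()] (or a list with
#'   `position`, `time_s`, `fs`).
#' @param synergy A [synergy_model()].
#' @param fs_emg EMG sampling rate, Hz (default 1000).
#'
#' @return A list with `emg` (N x 6 matrix), `activation` (N x 6, the
#'   noise-free modulating signal), `time_s`, and `fs`.
#' @export
generate_emg <- function(trajectory, synergy, fs_emg = 1000) {
  if (!inherits(synergy, "synergy_model")) {
    stop_emg("`synergy` must be a synergy_model.", "emgdecode_input_error")
  }
  pos <- trajectory$position
  if (is.null(pos) || nrow(pos) < 2L) {
    stop_emg("`trajectory` must contain a non-empty position series.",
             "emgdecode_input_error")
  }
  lead_ms <- synergy$electromechanical_lead_ms
  if (lead_ms < 50 || lead_ms > 100) {
    stop_emg("Electromechanical lead outside [50, 100] ms.",
             "emgdecode_lead_error")
  }
  t_coarse <- trajectory$time_s
  t_fine <- seq(t_coarse[1L], t_coarse[length(t_coarse)], by = 1 / fs_emg)
  pos_fine <- vapply(1:3, function(a) {
    stats::approx(t_coarse, pos[, a], xout = t_fine)$y
  }, numeric(length(t_fine)))
  n <- length(t_fine)

  vel <- apply(pos_fine, 2, function(p) c(0, diff(p)) * fs_emg)
  drivers <- cbind(abs(vel), sqrt(rowSums(vel^2)))

  lead_samp <- round(lead_ms * fs_emg / 1000)
  # advance: activation at time t mirrors motion at t + lead
  shift_fw <- function(x) c(x[(lead_samp + 1L):n], rep(x[n], lead_samp))
  drivers_lead <- apply(drivers, 2, shift_fw)

  activation <- synergy$baseline_amplitude +
    drivers_lead %*% t(synergy$mapping_matrix)

  emg <- with_seed_(synergy$seed, {
    out <- matrix(0, n, 6L)
    for (ch in 1:6) {
      carrier <- bandpass_noise(n, synergy$carrier_band_hz, fs_emg)
      carrier <- carrier / mean(abs(carrier))
      out[, ch] <- activation[, ch] * carrier +
        stats::rnorm(n, sd = synergy$noise_sd)
    }
    out
  })
  list(emg = emg, activation = activation, time_s = t_fine, fs = fs_emg)
}

#' Construct a synchronized EMG + kinematics recording
#'
#' Bundles one trial of synthetic data: hand position at 60 Hz and
#' six-channel EMG at 1 kHz sharing a common time origin, plus trial
#' metadata (task, speed, trial index, cycle onsets, seed).
#'
#' @param profile A [task_profile()].
#' @param speed `"quick"` or `"slow"`.
#' @param synergy A [synergy_model()]; its `seed` is overridden by `seed`.
#' @param trial_index Integer trial label.
#' @param seed Integer seed used for both jitter and EMG synthesis.
#'
#' @return An object of class `emg_recording` with elements `emg`
#'   (N x 6), `position` (M x 3, cm), `fs_emg`, `fs_pos`, `activation`,
#'   and `metadata`.
#' @export
simulate_recording <- function(profile, speed, synergy = synergy_model(),
                               trial_index = 1L, seed = 1L) {
  traj <- generate_trajectory(profile, speed, seed = derive_seed(seed, "traj"))
  syn <- synergy
  syn$seed <- derive_seed(seed, "emg")
  e <- generate_emg(traj, syn)
  structure(
    list(
      emg = e$emg,
      position = traj$position,
      fs_emg = e$fs,
      fs_pos = traj$fs,
      activation = e$activation,
      metadata = list(
        task_id = profile$task_id,
        speed = speed,
        trial_index = as.integer(trial_index),
        seed = as.integer(seed),
        cycle_onsets_s = traj$cycle_onsets_s,
        cycle_duration_s = profile$cycle_duration_s[[speed]],
        break_s = profile$break_s,
        cycles_per_trial = profile$cycles_per_trial,
        workspace_extent = profile$workspace_extent,
        electromechanical_lead_ms = synergy$electromechanical_lead_ms
      )
    ),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<emg_recording> %s / %s / trial %d: %d EMG samples @%g Hz (6 ch), %d position samples @%g Hz\n",
    md$task_id, md$speed, md$trial_index,
    nrow(x$emg), x$fs_emg, nrow(x$position), x$fs_pos
  ))
  invisible(x)
}

#' Default configuration for a full synthetic experiment
#'
#' @param tasks Character vector of built-in task ids.
#' @param speeds Character vector of speed conditions.
#' @param trials_per_condition Trials per task x speed cell (default 9,
#'   giving 2 x 2 x 9 = 36 recordings).
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @param synergy A [synergy_model()].
#'
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(tasks = c("Task_1", "Task_2"),
                              speeds = c("quick", "slow"),
                              trials_per_condition = 9L,
                              seed = 1L,
                              synergy = synergy_model()) {
  structure(
    list(tasks = tasks, speeds = speeds,
         trials_per_condition = as.integer(trials_per_condition),
         seed = as.integer(seed), synergy = synergy),
    class = "experiment_config"
  )
}

#' Generate a full synthetic experiment
#'
#' One recording per (task, speed, trial) cell; the default configuration
#' yields 36 recordings (2 tasks x 2 speeds x 9 trials). Per-trial seeds
#' are derived deterministically from the master seed, so identical
#' configurations reproduce identical recording sets bit-exactly.
#'
#' @param config An [experiment_config()].
#'
#' @return A list of [simulate_recording()] objects with class
#'   `emg_experiment`.
#' @export
generate_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config")) {
    stop_emg("`config` must be an experiment_config.", "emgdecode_input_error")
  }
  recs <- list()
  for (task in config$tasks) {
    profile <- task_profile(task)
    for (speed in config$speeds) {
      for (trial in seq_len(config$trials_per_condition)) {
        seed_t <- derive_seed(config$seed, task, speed, trial)
        recs[[length(recs) + 1L]] <- simulate_recording(
          profile, speed, config$synergy, trial_index = trial, seed = seed_t
        )
      }
    }
  }
  structure(recs, class = "emg_experiment")
}
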