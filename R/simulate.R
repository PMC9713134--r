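# synthetic multi-IMU gait trial generator with analytic ground truth

# right-arm pitch-range population parameters (control, vestibular), rad;
# the left arm is parameterized through sim_config (headline placement)
RIGHT_ARM_PITCH <- c(0.35, 0.26)
RIGHT_ARM_PITCH_SD <- c(0.14, 0.11)
ARM_ROLL_RANGE <- 0.13   # rad, identical distribution in both classes
ARM_ROLL_SD <- 0.04      # trial-level roll variability, class-independent
GRAVITY <- 9.81          # m/s^2
SWING_FRACTION <- 0.4    # swing duration as a fraction of stride time
FOOT_PITCH_RATE <- 3     # rad/s peak foot pitch rate during swing

participant_ids <- function(config) {
  c(sprintf("V%02d", seq_len(config$n_per_class)),
    sprintf("C%02d", seq_len(config$n_per_class)))
}

label_from_id <- function(participant_id) {
  as.integer(startsWith(participant_id, "V"))
}

# participant-level random effects: drawn once per participant so trials of
# one participant are correlated and subject-wise splitting matters
draw_participant_effects <- function(config, label) {
  cls <- label + 1L
  gap_len <- abs(diff(config$stride_length_mean))
  gap_time <- abs(diff(config$stride_time_mean))
  list(
    arm_left = rnorm(1, 0, config$arm_pitch_range_sd[cls] / sqrt(2)),
    arm_right = rnorm(1, 0, RIGHT_ARM_PITCH_SD[cls] / sqrt(2)),
    stride_length = rnorm(1, 0, gap_len / 2),
    stride_time = rnorm(1, 0, gap_time / 2),
    sway = rnorm(1, 0, 0.25)  # log-scale head/trunk/leg sway amplitude
  )
}

# class mean shifted toward the control value when the task contrast < 1
contrast_mean <- function(control, vestibular, label, contrast) {
  if (label == 1L) control - contrast * (control - vestibular) else control
}

# swing windows for one foot over the walking segment; returns per-swing
# start times and the stationary (stance) intervals around them
foot_schedule <- function(t0, t_end, stride_time, phase_offset) {
  S <- SWING_FRACTION * stride_time
  first <- t0 + 0.3 * stride_time + phase_offset
  starts <- seq(first, t_end - S - 0.05, by = stride_time)
  if (length(starts) < 1L) {
    abort("Trial too short for a single swing phase.",
          class = "vestigait_error_invalid_config")
  }
  stationary <- cbind(c(0, starts + S), c(starts, t_end))
  list(swing_starts = starts, swing_duration = S, stationary = stationary)
}

#' Simulate one multi-IMU gait trial
#'
#' Generates a trial that begins with quiet standing (`static_lead_in`
#' seconds) followed by periodic straight-line gait. Foot kinematics
#' alternate stance phases (velocity exactly zero in ground truth) and
#' raised-cosine swing bumps whose integral equals the drawn stride length;
#' arm gyroscopes carry a pitch sinusoid at stride frequency whose integrated
#' range equals the drawn arm pitch range. Body-frame signals are projected
#' into each sensor's frame through a random mounting rotation, then linear
#' gyro bias drift and white noise are added.
#'
#' @param config A [sim_config()].
#' @param participant_id ID starting with "V" (vestibular) or "C" (control).
#' @param task_id One of `config$tasks`.
#' @param trial_index Trial number within the task.
#' @param seed Optional integer seed; when `NULL` the current RNG state is used.
#' @param effects Optional participant random effects (drawn if `NULL`).
#' @param placements Placements to simulate (default all 13).
#' @return List with elements `recording` (a `trial_recording`) and `truth`
#'   (a `trial_truth` holding per-stride ground truth, true arm pitch ranges,
#'   mounting rotations and the noise-free foot velocity).
#' @export
simulate_trial <- function(config, participant_id, task_id, trial_index = 1L,
                           seed = NULL, effects = NULL,
                           placements = vestigait_placements()) {
  validate_sim_config(config)
  if (!task_id %in% config$tasks) {
    abort(sprintf("Task '%s' not in config$tasks.", task_id),
          class = "vestigait_error_invalid_config")
  }
  stopifnot(all(placements %in% vestigait_placements()))
  if (!is.null(seed)) set.seed(seed)
  label <- label_from_id(participant_id)
  cls <- label + 1L
  prof <- task_profile(task_id)
  if (is.null(effects)) effects <- draw_participant_effects(config, label)

  fs <- config$fs
  dur <- config$trial_duration
  t0 <- config$static_lead_in
  n <- round(fs * dur)
  t <- (seq_len(n) - 1) / fs
  walking <- t >= t0

  # trial-level kinematic draws
  L_mean <- contrast_mean(config$stride_length_mean[1], config$stride_length_mean[2],
                          label, prof$contrast) * prof$len + effects$stride_length
  T_mean <- contrast_mean(config$stride_time_mean[1], config$stride_time_mean[2],
                          label, prof$contrast) * prof$time + effects$stride_time
  L_trial <- max(rnorm(1, L_mean, config$stride_length_sd), 0.3)
  T_trial <- max(rnorm(1, T_mean, config$stride_time_sd), 0.5)
  f_stride <- 1 / T_trial

  # floor keeps the pitch swing dominant over the (class-shared) roll sway,
  # so the PCA frontal axis stays identifiable for every simulated trial
  arm_sd <- config$arm_pitch_range_sd[cls] / sqrt(2)
  range_left <- max(contrast_mean(config$arm_pitch_range[1], config$arm_pitch_range[2],
                                  label, prof$contrast) +
                      effects$arm_left + rnorm(1, 0, arm_sd), 0.15)
  range_right <- max(contrast_mean(RIGHT_ARM_PITCH[1], RIGHT_ARM_PITCH[2],
                                   label, prof$contrast) +
                       effects$arm_right +
                       rnorm(1, 0, RIGHT_ARM_PITCH_SD[cls] / sqrt(2)), 0.15)
  # roll sway draws share one distribution across classes; the cap at 0.8 x
  # pitch keeps the pitch axis dominant for the alignment PCA
  draw_roll <- function(base, pitch) {
    min(max(rnorm(1, base, ARM_ROLL_SD), 0.02), 0.8 * pitch)
  }
  roll_left <- draw_roll(ARM_ROLL_RANGE, range_left)
  roll_right <- draw_roll(ARM_ROLL_RANGE, range_right)

  # --- foot kinematics -------------------------------------------------
  feet <- list(left_foot = 0, right_foot = T_trial / 2)
  foot_truth <- list()
  foot_signals <- list()
  for (foot in names(feet)) {
    sch <- foot_schedule(t0, dur, T_trial, feet[[foot]])
    S <- sch$swing_duration
    n_sw <- length(sch$swing_starts)
    Lk <- pmax(rnorm(n_sw, L_trial, config$stride_length_cv * L_trial), 0.1)
    vx <- numeric(n)
    ax <- numeric(n)
    wy <- numeric(n)
    for (k in seq_len(n_sw)) {
      idx <- which(t >= sch$swing_starts[k] & t < sch$swing_starts[k] + S)
      tau <- t[idx] - sch$swing_starts[k]
      vx[idx] <- (Lk[k] / S) * (1 - cos(2 * pi * tau / S))
      ax[idx] <- (2 * pi * Lk[k] / S^2) * sin(2 * pi * tau / S)
      wy[idx] <- FOOT_PITCH_RATE * sin(pi * tau / S)
    }
    anchors <- rowMeans(sch$stationary)
    foot_truth[[foot]] <- list(
      footfall_times = anchors,
      stride_lengths = Lk,
      stride_times = diff(anchors),
      stationary_intervals = sch$stationary,
      velocity = cbind(x = vx, y = 0, z = 0)
    )
    foot_signals[[foot]] <- list(ax = ax, wy = wy)
  }

  # --- upper-body oscillation amplitudes -------------------------------
  # an angular-rate sinusoid A*sin(2*pi*g*t) integrates to a displacement of
  # range A/(pi*g); amplitudes are chosen from target displacement ranges
  pitch_amp <- function(range, freq) range * pi * freq
  # head/trunk/leg sway varies across participants and trials through a
  # shared multiplicative factor (applied to pitch and roll jointly, so the
  # pitch-dominance ratio used by the axis PCA is preserved)
  sway_scale <- exp(effects$sway + rnorm(1, 0, 0.2))
  segment_pitch_range <- list(
    head = contrast_mean(0.10, 0.07, label, prof$contrast) * sway_scale,
    upper_back = contrast_mean(0.12, 0.09, label, prof$contrast) * sway_scale,
    lower_back = contrast_mean(0.10, 0.085, label, prof$contrast) * sway_scale,
    left_arm = range_left, right_arm = range_right,
    left_wrist = 1.1 * range_left, right_wrist = 1.1 * range_right,
    left_thigh = 0.45 * L_trial / 1.2 * sway_scale,
    right_thigh = 0.45 * L_trial / 1.2 * sway_scale,
    left_shank = 0.9 * L_trial / 1.2 * sway_scale,
    right_shank = 0.9 * L_trial / 1.2 * sway_scale
  )
  segment_roll_range <- list(
    head = 0.03 * sway_scale, upper_back = 0.035 * sway_scale,
    lower_back = 0.035 * sway_scale,
    left_arm = roll_left, right_arm = roll_right,
    left_wrist = draw_roll(0.10, 1.1 * range_left),
    right_wrist = draw_roll(0.10, 1.1 * range_right),
    left_thigh = 0.08 * sway_scale, right_thigh = 0.08 * sway_scale,
    left_shank = 0.08 * sway_scale, right_shank = 0.08 * sway_scale
  )
  # roll sway sits at stride frequency for the pendular arm/wrist segments
  # and at step frequency (2x stride) for head, trunk and legs; quadrature
  # phase keeps the projected pitch/roll covariance diagonal
  roll_freq_mult <- function(p) {
    if (grepl("arm|wrist", p)) 1 else 2
  }
  side_phase <- function(p) if (startsWith(p, "right")) pi else 0

  tw <- pmax(t - t0, 0)
  mounting <- list()
  recording <- list()
  for (p in placements) {
    acc <- matrix(0, n, 3)
    gyr <- matrix(0, n, 3)
    acc[, 3] <- GRAVITY
    if (p %in% names(foot_signals)) {
      acc[, 1] <- acc[, 1] + foot_signals[[p]]$ax
      gyr[, 2] <- gyr[, 2] + foot_signals[[p]]$wy
    } else {
      fr <- roll_freq_mult(p) * f_stride
      Ap <- pitch_amp(segment_pitch_range[[p]], f_stride)
      Ar <- pitch_amp(segment_roll_range[[p]], fr)
      gyr[walking, 2] <- Ap * sin(2 * pi * f_stride * tw[walking] + side_phase(p))
      gyr[walking, 1] <- Ar * sin(2 * pi * fr * tw[walking] + pi / 2)
      if (p == "head" && prof$head_turn != "none") {
        sq <- 0.7 * sign(sin(2 * pi * tw[walking] / (3 * T_trial)))
        ax_turn <- if (prof$head_turn == "pitch") 2L else 3L
        gyr[walking, ax_turn] <- gyr[walking, ax_turn] + sq
      }
    }
    R <- rotvec_to_matrix(rnorm(3, 0, config$mounting_rotation_sd))
    mounting[[p]] <- R
    # sensor-frame measurement: v_sensor = R' v_body  (v_body = R v_sensor)
    acc_s <- acc %*% R
    gyr_s <- gyr %*% R
    slope <- rnorm(3, 0, config$gyro_bias_drift)
    gyr_s <- gyr_s + outer(t, slope)
    if (config$accel_noise_sd > 0) {
      acc_s <- acc_s + matrix(rnorm(3 * n, 0, config$accel_noise_sd), n, 3)
    }
    if (config$gyro_noise_sd > 0) {
      gyr_s <- gyr_s + matrix(rnorm(3 * n, 0, config$gyro_noise_sd), n, 3)
    }
    colnames(acc_s) <- c("x", "y", "z")
    colnames(gyr_s) <- c("x", "y", "z")
    recording[[p]] <- list(acc = acc_s, gyr = gyr_s)
  }

  rec <- structure(list(
    participant_id = participant_id, task_id = task_id,
    trial_index = as.integer(trial_index), label = label,
    fs = fs, static_lead_in = t0, placements = recording
  ), class = "trial_recording")
  truth <- structure(list(
    participant_id = participant_id, task_id = task_id,
    trial_index = as.integer(trial_index), label = label,
    stride_length_trial = L_trial, stride_time_trial = T_trial,
    feet = foot_truth,
    arm_pitch_range = c(left = range_left, right = range_right),
    mounting = mounting
  ), class = "trial_truth")
  list(recording = rec, truth = truth)
}

#' Simulate a labeled gait cohort
#'
#' Draws `2 * n_per_class` participants with per-participant random effects,
#' then simulates `trials_per_task` trials of every configured task for each
#' participant. The whole draw is controlled by `config$seed`, so identical
#' configurations produce bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @param placements Placements to simulate (default all 13).
#' @return A `gait_cohort` list: `trials` (list of `trial_recording`),
#'   `truths` (list of `trial_truth`), `manifest` (tibble keyed by
#'   participant, task, trial with labels), and the `config`.
#' @export
simulate_cohort <- function(config, placements = vestigait_placements()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ids <- participant_ids(config)
  effects <- lapply(ids, function(id) draw_participant_effects(config, label_from_id(id)))
  names(effects) <- ids

  trials <- list()
  truths <- list()
  rows <- list()
  i <- 0L
  for (id in ids) {
    for (task in config$tasks) {
      for (k in seq_len(config$trials_per_task)) {
        i <- i + 1L
        sim <- simulate_trial(config, id, task, k,
                              effects = effects[[id]], placements = placements)
        trials[[i]] <- sim$recording
        truths[[i]] <- sim$truth
        rows[[i]] <- tibble(participant_id = id, task_id = task,
                            trial_index = k,
                            label = label_from_id(id), index = i)
      }
    }
  }
  structure(list(trials = trials, truths = truths,
                 manifest = list_rbind(rows), config = config),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials, %d participants, tasks: %s\n",
              length(x$trials), length(unique(x$manifest$participant_id)),
              paste(unique(x$manifest$task_id), collapse = ", ")))
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- nrow(x$placements[[1]]$acc)
  cat(sprintf("<trial_recording> %s / %s / trial %d, label %d, %d placements, %d samples @ %g Hz\n",
              x$participant_id, x$task_id, x$trial_index, x$label,
              length(x$placements), n, x$fs))
  invisible(x)
}
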