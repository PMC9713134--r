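# study-protocol constants and the simulation configuration

#' Canonical IMU placements
#'
#' The 13 body placements of the full-body sensor set: head, upper back,
#' lower back, and left/right arm, wrist, thigh, shank, foot.
#'
#' @return Character vector of placement names.
#' @export
vestigait_placements <- function() {
  c("head", "upper_back", "lower_back",
    "left_arm", "right_arm", "left_wrist", "right_wrist",
    "left_thigh", "right_thigh", "left_shank", "right_shank",
    "left_foot", "right_foot")
}

#' Canonical gait task identifiers
#'
#' The seven walkway tasks: self-selected speed (SSGS), change of speed
#' (CGS), vertical head turns (GVHT), horizontal head turns (GHHT), eyes
#' closed (GEC), fast (FGS) and slow (SLGS) gait.
#'
#' @return Character vector of task IDs.
#' @export
vestigait_tasks <- function() {
  c("SSGS", "CGS", "GVHT", "GHHT", "GEC", "FGS", "SLGS")
}

#' Simulation configuration for the synthetic gait cohort
#'
#' Defines the cohort layout (participants per class, tasks, trials), the
#' recording protocol (sampling rate, trial duration, static lead-in) and the
#' kinematic population parameters per class. Class-parameter vectors are
#' ordered `c(control, vestibular)`. Defaults encode the emulated study
#' conditions: 15 participants per class, 7 tasks x 3 trials at 128 Hz, and a
#' left-arm pitch-swing contrast of 0.49 (SD 0.21) vs 0.26 (SD 0.11) rad
#' during eyes-closed walking.
#'
#' @param n_per_class Participants per class.
#' @param tasks Task IDs to simulate (subset of [vestigait_tasks()]).
#' @param trials_per_task Trials per participant and task.
#' @param fs Sampling rate in Hz.
#' @param trial_duration Trial length in seconds (includes the static lead-in).
#' @param static_lead_in Quiet-standing segment at the start of each trial, s.
#' @param stride_length_mean Class mean stride length, m, `c(control, vestibular)`.
#' @param stride_time_mean Class mean stride time, s.
#' @param stride_length_sd Trial-level stride length SD, m.
#' @param stride_time_sd Trial-level stride time SD, s.
#' @param stride_length_cv Within-trial per-stride relative variation.
#' @param arm_pitch_range Class mean left-arm pitch displacement range, rad.
#' @param arm_pitch_range_sd Class SD of the left-arm pitch range, rad.
#' @param accel_noise_sd Accelerometer white-noise SD, m/s^2.
#' @param gyro_noise_sd Gyroscope white-noise SD, rad/s.
#' @param gyro_bias_drift SD of the per-axis linear gyro bias slope, rad/s per s.
#' @param mounting_rotation_sd SD of the random sensor mounting rotation
#'   vector, rad, per placement.
#' @param seed Integer seed controlling the whole cohort draw.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_per_class = 15,
                       tasks = vestigait_tasks(),
                       trials_per_task = 3,
                       fs = 128,
                       trial_duration = 12,
                       static_lead_in = 2,
                       stride_length_mean = c(control = 1.25, vestibular = 1.05),
                       stride_time_mean = c(control = 1.05, vestibular = 1.15),
                       stride_length_sd = 0.03,
                       stride_time_sd = 0.02,
                       stride_length_cv = 0.02,
                       arm_pitch_range = c(control = 0.49, vestibular = 0.26),
                       arm_pitch_range_sd = c(control = 0.21, vestibular = 0.11),
                       accel_noise_sd = 0.05,
                       gyro_noise_sd = 0.02,
                       gyro_bias_drift = 0.001,
                       mounting_rotation_sd = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_per_class = as.integer(n_per_class), tasks = tasks,
    trials_per_task = as.integer(trials_per_task), fs = fs,
    trial_duration = trial_duration, static_lead_in = static_lead_in,
    stride_length_mean = stride_length_mean,
    stride_time_mean = stride_time_mean,
    stride_length_sd = stride_length_sd, stride_time_sd = stride_time_sd,
    stride_length_cv = stride_length_cv,
    arm_pitch_range = arm_pitch_range,
    arm_pitch_range_sd = arm_pitch_range_sd,
    accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
    gyro_bias_drift = gyro_bias_drift,
    mounting_rotation_sd = mounting_rotation_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos <- c("n_per_class", "trials_per_task", "fs", "trial_duration",
           "static_lead_in")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      abort(sprintf("sim_config field '%s' must be a positive scalar.", f),
            class = "vestigait_error_invalid_config")
    }
  }
  for (f in c("stride_length_mean", "stride_time_mean", "arm_pitch_range",
              "arm_pitch_range_sd")) {
    if (length(cfg[[f]]) != 2L || any(!is.finite(cfg[[f]])) || any(cfg[[f]] < 0)) {
      abort(sprintf("sim_config field '%s' must be length-2 (control, vestibular).", f),
            class = "vestigait_error_invalid_config")
    }
  }
  if (!all(cfg$tasks %in% vestigait_tasks())) {
    abort("Unknown task ID in sim_config$tasks.",
          class = "vestigait_error_invalid_config")
  }
  n <- cfg$fs * cfg$trial_duration
  if (abs(n - round(n)) > 1e-9) {
    abort("fs * trial_duration must be an integer sample count.",
          class = "vestigait_error_invalid_config")
  }
  if (cfg$static_lead_in >= cfg$trial_duration) {
    abort("static_lead_in must be shorter than trial_duration.",
          class = "vestigait_error_invalid_config")
  }
  cfg
}

# Per-task kinematic profile. Speed factors scale stride time/length for both
# classes; `contrast` scales how far the vestibular class departs from the
# control class (eyes-closed walking shows the full contrast, all other tasks
# a reduced one); head-turn tasks add a square-wave head rotation.
task_profile <- function(task_id) {
  profiles <- list(
    SSGS = list(time = 1.00, len = 1.00, contrast = 0.35, head_turn = "none"),
    CGS  = list(time = 1.05, len = 0.95, contrast = 0.35, head_turn = "none"),
    GVHT = list(time = 1.00, len = 1.00, contrast = 0.35, head_turn = "pitch"),
    GHHT = list(time = 1.00, len = 1.00, contrast = 0.35, head_turn = "yaw"),
    GEC  = list(time = 1.00, len = 1.00, contrast = 1.00, head_turn = "none"),
    FGS  = list(time = 0.85, len = 1.15, contrast = 0.35, head_turn = "none"),
    SLGS = list(time = 1.30, len = 0.70, contrast = 0.35, head_turn = "none")
  )
  p <- profiles[[task_id]]
  if (is.null(p)) {
    abort(sprintf("Unknown task '%s'.", task_id),
          class = "vestigait_error_invalid_config")
  }
  p
}
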