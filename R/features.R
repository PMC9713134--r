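# the 590-feature kinematic descriptor scheme and per-task dataset assembly

DESCRIPTOR_NAMES <- c("max", "min", "mean", "rms", "range")
CHANNEL_NAMES <- c("gyr_x", "gyr_y", "gyr_z", "acc_x", "acc_y", "acc_z",
                   "gyr_total", "acc_total")
TRUNK_PLACEMENTS <- c("head", "upper_back", "lower_back")
FOOT_PLACEMENTS <- c("left_foot", "right_foot")
STRIDE_FEATURES <- c("stride_length_mean", "stride_length_var",
                     "stride_time_mean", "stride_time_var",
                     "stride_frequency_mean", "foot_speed_mean")

#' Canonical feature specification
#'
#' Ordered feature names per placement: 5 statistical descriptors (maximum,
#' minimum, mean, RMS, range) for each of 3 gyro axes, 3 accel axes and the
#' two total magnitudes (40), plus mean and range of pitch and roll angular
#' displacement (44); head/upper back/lower back add the 95% sway ellipse
#' areas of angular velocity and displacement (46); feet add the six
#' spatiotemporal stride summaries (50). Over 13 placements: 590 features.
#'
#' @param placements Placements to include (default all 13).
#' @return A `feature_spec`: named list of per-placement feature names plus
#'   the total count.
#' @export
feature_spec <- function(placements = vestigait_placements()) {
  stopifnot(all(placements %in% vestigait_placements()))
  per_placement <- lapply(placements, function(p) {
    base <- c(t(outer(CHANNEL_NAMES, DESCRIPTOR_NAMES, paste, sep = "_")))
    base <- c(base, "pitch_mean", "pitch_range", "roll_mean", "roll_range")
    if (p %in% TRUNK_PLACEMENTS) {
      base <- c(base, "sway_velocity_ea", "sway_displacement_ea")
    }
    if (p %in% FOOT_PLACEMENTS) base <- c(base, STRIDE_FEATURES)
    base
  })
  names(per_placement) <- placements
  counts <- lengths(per_placement)
  expected <- ifelse(placements %in% TRUNK_PLACEMENTS, 46L,
                     ifelse(placements %in% FOOT_PLACEMENTS, 50L, 44L))
  stopifnot(all(counts == expected))
  if (setequal(placements, vestigait_placements())) stopifnot(sum(counts) == 590L)
  structure(list(placement_features = per_placement,
                 placements = placements, n_total = sum(counts)),
            class = "feature_spec")
}

#' Statistical descriptors of a series
#'
#' @param x Nonempty finite numeric vector.
#' @return Named vector: max, min, mean, rms, range (= max - min).
#' @export
descriptors <- function(x) {
  if (length(x) == 0L) {
    abort("Cannot summarize an empty series.", class = "vestigait_error_empty_input")
  }
  mx <- max(x); mn <- min(x)
  c(max = mx, min = mn, mean = mean(x),
    rms = sqrt(mean(x^2)), range = mx - mn)
}

#' Elementwise total magnitude of a tri-axial signal
#'
#' @param x,y,z Equal-length numeric vectors.
#' @return `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
total_magnitude <- function(x, y, z) {
  if (length(y) != length(x) || length(z) != length(x)) {
    abort("Axis series must have equal length.", class = "vestigait_error_shape")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' 95% confidence ellipse area of paired samples
#'
#' Area of the 95% confidence ellipse of the bivariate sample (u, v):
#' `pi * chi2_2(0.95) * sqrt(lambda1 * lambda2)` with lambda the eigenvalues
#' of the 2 x 2 sample covariance (equivalently `sqrt(det)`). A degenerate
#' covariance gives area 0.
#'
#' @param u,v Numeric vectors (>= 10 samples).
#' @return Ellipse area (units of u times units of v).
#' @export
ellipse_area_95 <- function(u, v) {
  if (length(u) < 10L || length(v) != length(u)) {
    abort("ellipse_area_95 needs >= 10 paired samples.",
          class = "vestigait_error_empty_input")
  }
  d <- det(cov(cbind(u, v)))
  if (!is.finite(d) || d <= 0) return(0)
  pi * qchisq(0.95, df = 2) * sqrt(d)
}

placement_features <- function(acc, gyr, fs, static_lead_in, placement,
                               spec, filter, thresholds) {
  pre <- preprocess_signals(acc, gyr, fs, static_lead_in, filter)
  gt <- total_magnitude(pre$gyr_f[, 1], pre$gyr_f[, 2], pre$gyr_f[, 3])
  at <- total_magnitude(pre$acc_f[, 1], pre$acc_f[, 2], pre$acc_f[, 3])
  channels <- list(
    gyr_x = pre$gyr_f[, 1], gyr_y = pre$gyr_f[, 2], gyr_z = pre$gyr_f[, 3],
    acc_x = pre$acc_f[, 1], acc_y = pre$acc_f[, 2], acc_z = pre$acc_f[, 3],
    gyr_total = gt, acc_total = at
  )
  vals <- unlist(lapply(names(channels), function(ch) {
    d <- descriptors(channels[[ch]])
    setNames(d, paste(ch, names(d), sep = "_"))
  }))
  theta_y <- pre$theta[, "y"]
  theta_x <- pre$theta[, "x"]
  vals <- c(vals,
            pitch_mean = mean(theta_y), pitch_range = diff(range(theta_y)),
            roll_mean = mean(theta_x), roll_range = diff(range(theta_x)))
  if (placement %in% TRUNK_PLACEMENTS) {
    vals <- c(vals,
              sway_velocity_ea = ellipse_area_95(pre$gyr_f[, 2], pre$gyr_f[, 1]),
              sway_displacement_ea = ellipse_area_95(theta_y, theta_x))
  }
  if (placement %in% FOOT_PLACEMENTS) {
    fw <- foot_strides(acc, gyr, fs, static_lead_in, thresholds)
    s <- fw$strides$summary
    vals <- c(vals, unlist(s[1, STRIDE_FEATURES]))
  }
  expected <- spec$placement_features[[placement]]
  vals <- vals[match(expected, names(vals))]
  names(vals) <- expected
  vals
}

#' Extract the named feature vector for one trial
#'
#' Runs preprocessing per placement (descriptor features on the band-passed
#' walking segment, sway displacement from the integrated filtered angular
#' rate) and the raw-signal ZUPT chain for the feet, then assembles the
#' canonical ordered feature vector. Any non-finite feature aborts with the
#' offending feature named.
#'
#' @param trial A `trial_recording`.
#' @param spec A [feature_spec()]; only placements present in both the spec
#'   and the trial are extracted.
#' @param filter A [filter_spec()].
#' @param thresholds A [stationary_thresholds()].
#' @return One-row tibble: trial key columns (`participant_id`, `task_id`,
#'   `trial_index`, `label`) then `<placement>_<feature>` columns.
#' @export
extract_features <- function(trial, spec = feature_spec(),
                             filter = filter_spec(),
                             thresholds = stationary_thresholds()) {
  placements <- intersect(spec$placements, names(trial$placements))
  if (length(placements) == 0L) {
    abort("No spec placement present in the trial.",
          class = "vestigait_error_empty_input")
  }
  all_vals <- unlist(lapply(placements, function(p) {
    v <- placement_features(trial$placements[[p]]$acc, trial$placements[[p]]$gyr,
                            trial$fs, trial$static_lead_in %||% 2, p,
                            spec, filter, thresholds)
    setNames(v, paste(p, names(v), sep = "_"))
  }))
  bad <- names(all_vals)[!is.finite(all_vals)]
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite feature(s) in trial %s/%s/%d: %s",
                  trial$participant_id, trial$task_id, trial$trial_index,
                  paste(bad, collapse = ", ")),
          class = "vestigait_error_nonfinite_feature")
  }
  bind_cols(
    tibble(participant_id = trial$participant_id, task_id = trial$task_id,
           trial_index = trial$trial_index, label = trial$label),
    as_tibble(as.list(all_vals))
  )
}

#' Extract features for every trial of a cohort
#'
#' @param cohort A `gait_cohort`.
#' @inheritParams extract_features
#' @return Tibble with one row per trial.
#' @export
extract_cohort_features <- function(cohort, spec = feature_spec(),
                                    filter = filter_spec(),
                                    thresholds = stationary_thresholds()) {
  list_rbind(map(cohort$trials, extract_features,
                 spec = spec, filter = filter, thresholds = thresholds))
}

#' Assemble the per-task dataset
#'
#' Selects one gait task from a cohort feature table, in stable
#' (participant, trial) row order. For the emulated protocol this is the
#' 90 x 590 task dataset (30 participants x 3 trials, balanced classes).
#'
#' @param features Cohort feature tibble from [extract_cohort_features()].
#' @param task_id Task to select.
#' @param trials_per_participant Expected trials per participant; a mismatch
#'   warns with an explicit count (never silently).
#' @return Tibble of that task's rows, `task_id` attribute set.
#' @export
build_dataset <- function(features, task_id, trials_per_participant = NULL) {
  out <- features |>
    filter(.data$task_id == !!task_id) |>
    arrange(.data$participant_id, .data$trial_index)
  if (nrow(out) == 0L) {
    abort(sprintf("No trials for task '%s'.", task_id),
          class = "vestigait_error_empty_dataset")
  }
  if (!is.null(trials_per_participant)) {
    counts <- out |> count(.data$participant_id)
    short <- counts |> filter(.data$n != trials_per_participant)
    if (nrow(short) > 0L) {
      warn(sprintf("Task %s: %d participant(s) without %d trials (e.g. %s has %d).",
                   task_id, nrow(short), trials_per_participant,
                   short$participant_id[1], short$n[1]))
    }
  }
  attr(out, "task_id") <- task_id
  out
}

# names of the metadata (non-feature) columns of a dataset tibble
META_COLS <- c("participant_id", "task_id", "trial_index", "label")

feature_columns <- function(dataset, placement = NULL) {
  cols <- setdiff(names(dataset), META_COLS)
  if (!is.null(placement)) {
    cols <- cols[startsWith(cols, paste0(placement, "_"))]
  }
  cols
}
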