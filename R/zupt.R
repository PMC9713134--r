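# stationary-period detection, zero-velocity-update correction, stride parameters

#' Stationary-period detection thresholds
#'
#' A sample counts as stationary when the acceleration norm is within
#' `accel_tol` of g AND the angular rate norm is below `gyro_tol`. Runs
#' shorter than `min_stationary` are discarded; runs closer together than
#' `min_stride_time` are merged.
#'
#' @param accel_tol Bound on | ||a|| - g |, m/s^2.
#' @param gyro_tol Bound on ||omega||, rad/s.
#' @param min_stationary Minimum stance duration, s.
#' @param min_stride_time Minimum time between footfalls of one foot, s.
#' @return A `stationary_thresholds` list.
#' @export
stationary_thresholds <- function(accel_tol = 0.8, gyro_tol = 0.6,
                                  min_stationary = 0.08, min_stride_time = 0.3) {
  vals <- c(accel_tol, gyro_tol, min_stationary, min_stride_time)
  if (any(vals <= 0)) {
    abort("All stationary thresholds must be positive.",
          class = "vestigait_error_invalid_config")
  }
  structure(list(accel_tol = accel_tol, gyro_tol = gyro_tol,
                 min_stationary = min_stationary,
                 min_stride_time = min_stride_time),
            class = "stationary_thresholds")
}

#' Detect stationary foot periods and footfall anchors
#'
#' Runs on raw (unfiltered) body-frame foot signals: the band-pass would
#' remove gravity and destroy the ||a|| ~ g criterion. Each surviving
#' stationary run contributes one footfall anchor at its midpoint sample.
#'
#' @param acc,gyr Raw n x 3 body-frame matrices.
#' @param fs Sampling rate, Hz.
#' @param thresholds A [stationary_thresholds()].
#' @param g Gravitational acceleration, m/s^2.
#' @return A `footfall_events` list: logical `mask`, integer `anchors`
#'   (sample indices), and a `runs` tibble (start, end samples).
#' @export
detect_stationary <- function(acc, gyr, fs, thresholds = stationary_thresholds(),
                              g = GRAVITY) {
  mask <- abs(row_norms(as.matrix(acc)) - g) < thresholds$accel_tol &
    row_norms(as.matrix(gyr)) < thresholds$gyro_tol
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1L >= round(thresholds$min_stationary * fs), ]
  if (nrow(runs) > 1L) {
    gap_samples <- round(thresholds$min_stride_time * fs)
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < gap_samples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- bind_rows(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  if (nrow(runs) == 0L) {
    abort("No stationary periods detected.",
          class = "vestigait_error_no_footfalls")
  }
  anchors <- as.integer(floor((runs$start + runs$end) / 2))
  structure(list(mask = mask, anchors = anchors, runs = runs, fs = fs),
            class = "footfall_events")
}

#' Zero-velocity-update drift correction
#'
#' Removes gravity (g along body z), integrates acceleration to velocity,
#' then removes the integration error under the ZUPT assumptions: the foot
#' does not slip during footfalls (velocity = 0 there) and the drift between
#' consecutive footfalls is linear in time. The line through the integrated
#' velocities at the two bounding anchors is subtracted on each inter-anchor
#' interval, so the corrected velocity is exactly zero at every anchor.
#'
#' @param acc n x 3 body-frame acceleration (raw, gravity included).
#' @param events A `footfall_events` with at least 2 anchors.
#' @param fs Sampling rate, Hz.
#' @param g Gravitational acceleration, m/s^2.
#' @return n x 3 corrected velocity matrix, m/s.
#' @export
zupt_correct <- function(acc, events, fs, g = GRAVITY) {
  if (length(events$anchors) < 2L) {
    abort("ZUPT needs at least two footfall anchors.",
          class = "vestigait_error_insufficient_footfalls")
  }
  a <- as.matrix(acc)
  a[, 3] <- a[, 3] - g
  v <- cumtrapz_fs(a, fs)
  n <- nrow(v)
  idx <- seq_len(n)
  for (j in 1:3) {
    err <- approx(x = events$anchors, y = v[events$anchors, j],
                  xout = idx, rule = 2)$y
    v[, j] <- v[, j] - err
  }
  colnames(v) <- c("x", "y", "z")
  v
}

empty_stride_table <- function() {
  structure(list(
    strides = tibble(length = numeric(0), time = numeric(0)),
    summary = tibble(stride_length_mean = 0, stride_length_var = 0,
                     stride_time_mean = 0, stride_time_var = 0,
                     stride_frequency_mean = 0, foot_speed_mean = 0),
    v_footfall = 0
  ), class = "stride_table")
}

#' Spatiotemporal stride parameters from corrected foot velocity
#'
#' Position by trapezoidal integration of the ZUPT-corrected velocity.
#' Stride length is the planar (x-y) displacement between consecutive
#' footfall anchors; stride time the anchor time difference; stride
#' frequency the mean of 1/stride time; foot speed the total planar path
#' length between first and last anchors divided by the elapsed time.
#'
#' @param velocity n x 3 corrected velocity from [zupt_correct()].
#' @param events A `footfall_events`.
#' @param fs Sampling rate, Hz.
#' @return A `stride_table`: per-stride tibble plus the summary features
#'   (means/variances, frequency, speed) and the zero-velocity constraint
#'   value `v_footfall = 0`.
#' @export
compute_strides <- function(velocity, events, fs) {
  anchors <- events$anchors
  if (length(anchors) < 2L) return(empty_stride_table())
  pos <- cumtrapz_fs(velocity, fs)
  planar <- pos[, 1:2, drop = FALSE]
  lengths <- sqrt(rowSums((planar[anchors[-1], , drop = FALSE] -
                             planar[anchors[-length(anchors)], , drop = FALSE])^2))
  times <- diff(anchors) / fs
  span <- anchors[1]:anchors[length(anchors)]
  speed <- sqrt(rowSums(velocity[span, 1:2, drop = FALSE]^2))
  path_len <- sum((speed[-1] + speed[-length(speed)]) / 2) / fs
  elapsed <- (anchors[length(anchors)] - anchors[1]) / fs
  structure(list(
    strides = tibble(length = lengths, time = times),
    summary = tibble(
      stride_length_mean = mean(lengths),
      stride_length_var = if (length(lengths) > 1) var(lengths) else 0,
      stride_time_mean = mean(times),
      stride_time_var = if (length(times) > 1) var(times) else 0,
      stride_frequency_mean = mean(1 / times),
      foot_speed_mean = path_len / elapsed
    ),
    v_footfall = 0
  ), class = "stride_table")
}

#' Full foot pipeline: align, detect, correct, summarize
#'
#' Runs the foot-mounted IMU chain on raw sensor-frame signals: axis
#' alignment, stationary detection on the unfiltered body-frame signals,
#' ZUPT correction and stride parameters. Degenerate trials (fewer than two
#' detected footfalls) yield an empty stride table with a warning instead of
#' aborting, so cohort-level dataset assembly is total.
#'
#' @param acc,gyr Raw n x 3 sensor-frame matrices for the whole trial.
#' @param fs Sampling rate, Hz.
#' @param static_lead_in Quiet-standing lead-in, s.
#' @param thresholds A [stationary_thresholds()].
#' @return List: `strides` (a `stride_table`), `events`, `velocity`, `axes`.
#' @export
foot_strides <- function(acc, gyr, fs, static_lead_in = 2,
                         thresholds = stationary_thresholds()) {
  n_static <- round(static_lead_in * fs)
  z <- estimate_gravity_axis(acc[seq_len(n_static), , drop = FALSE])
  axes <- estimate_frontal_axis(gyr[(n_static + 1):nrow(gyr), , drop = FALSE], z)
  aligned <- align_axes(acc, gyr, axes)
  res <- tryCatch({
    events <- detect_stationary(aligned$acc, aligned$gyr, fs, thresholds)
    velocity <- zupt_correct(aligned$acc, events, fs)
    list(strides = compute_strides(velocity, events, fs),
         events = events, velocity = velocity)
  }, vestigait_error_no_footfalls = function(e) NULL,
     vestigait_error_insufficient_footfalls = function(e) NULL)
  if (is.null(res)) {
    warn("Fewer than two footfalls detected; stride features zeroed.")
    res <- list(strides = empty_stride_table(), events = NULL, velocity = NULL)
  }
  c(res, list(axes = axes))
}
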