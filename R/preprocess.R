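# sensor-to-body axis alignment, zero-phase band-pass, gyro integration

#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass used on all kinematic channels before
#' descriptor extraction. Defaults follow the standard biomechanics choice:
#' 0.5-25 Hz, 4th order, applied forward-backward.
#'
#' @param low,high Cutoff frequencies in Hz.
#' @param order Filter order (even; realized as `butter(order/2)` band-pass).
#' @param zero_phase Apply forward-backward (`filtfilt`)?
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low = 0.5, high = 25, order = 4, zero_phase = TRUE) {
  if (!(low > 0 && high > low)) {
    abort("filter_spec requires 0 < low < high.",
          class = "vestigait_error_invalid_config")
  }
  if (order %% 2 != 0) {
    abort("filter_spec order must be even.",
          class = "vestigait_error_invalid_config")
  }
  structure(list(low = low, high = high, order = order,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Estimate the gravity (z) axis from a static accelerometer segment
#'
#' The body z-axis in the sensor frame is the mean acceleration direction
#' over a quiet-standing segment, pointing "up" (positive dot product with
#' the measured gravity reaction).
#'
#' @param static_accel n x 3 accelerometer matrix (m/s^2) over the static
#'   segment (>= 0.5 s of samples).
#' @return Unit 3-vector.
#' @export
estimate_gravity_axis <- function(static_accel) {
  static_accel <- as.matrix(static_accel)
  m <- colMeans(static_accel)
  nm <- sqrt(sum(m^2))
  if (nm < 0.5 * GRAVITY) {
    abort("Mean static acceleration below 0.5 g; sensor likely moving.",
          class = "vestigait_error_no_static_gravity")
  }
  m / nm
}

#' Estimate body-frame axes from walking gyroscope data
#'
#' Projects the angular velocity onto the plane orthogonal to the gravity
#' axis and takes the first principal direction of the projected 2-D samples
#' as the frontal (y) axis; the sagittal axis is x = y x z. The y sign is
#' fixed so the mean angular velocity about y over the walking segment is
#' non-negative (a deterministic convention applied identically to both
#' classes), and the frame is re-orthonormalized right-handed.
#'
#' @param walking_gyro n x 3 gyroscope matrix (rad/s) over walking.
#' @param z Unit gravity axis from [estimate_gravity_axis()].
#' @return A `body_frame_axes` list with unit vectors `x`, `y`, `z`.
#' @export
estimate_frontal_axis <- function(walking_gyro, z) {
  walking_gyro <- as.matrix(walking_gyro)
  z <- unit_vector(z)
  seed_vec <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vector(seed_vec - sum(seed_vec * z) * z)
  e2 <- cross3(z, e1)
  proj <- walking_gyro %*% cbind(e1, e2)
  C <- cov(proj)
  ev <- eigen(C, symmetric = TRUE)
  if (ev$values[2] > 0 && ev$values[1] / ev$values[2] < 1.05) {
    abort("Projected gyro covariance is near-isotropic; frontal axis ambiguous.",
          class = "vestigait_error_ambiguous_axes")
  }
  y <- ev$vectors[1, 1] * e1 + ev$vectors[2, 1] * e2
  if (mean(walking_gyro %*% y) < 0) y <- -y
  y <- unit_vector(y - sum(y * z) * z)
  x <- unit_vector(cross3(y, z))
  structure(list(x = x, y = y, z = z), class = "body_frame_axes")
}

#' Rotate raw signals into the body frame
#'
#' Pure rotation: per-sample vector norms are preserved.
#'
#' @param acc,gyr n x 3 matrices in the sensor frame.
#' @param axes A `body_frame_axes` object.
#' @return List with rotated `acc` and `gyr` (columns x, y, z).
#' @export
align_axes <- function(acc, gyr, axes) {
  B <- cbind(axes$x, axes$y, axes$z)
  out <- list(acc = as.matrix(acc) %*% B, gyr = as.matrix(gyr) %*% B)
  colnames(out$acc) <- c("x", "y", "z")
  colnames(out$gyr) <- c("x", "y", "z")
  out
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward (when `zero_phase`), so
#' the passband is preserved without phase shift and DC/drift is removed.
#'
#' @param x Numeric vector or n x k matrix (filtered per column).
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, Hz.
#' @return Filtered series, same shape as `x`.
#' @export
bandpass <- function(x, spec = filter_spec(), fs) {
  if (spec$high >= fs / 2) {
    abort("filter_spec high cutoff must be below fs/2.",
          class = "vestigait_error_invalid_config")
  }
  m <- as.matrix(x)
  min_len <- 9 * (2 * spec$order + 1)
  if (nrow(m) <= min_len) {
    abort(sprintf("Series too short to filter (need > %d samples).", min_len),
          class = "vestigait_error_filter_length")
  }
  bf <- butter(spec$order / 2, c(spec$low, spec$high) / (fs / 2), type = "pass")
  out <- apply(m, 2, function(col) {
    col <- col - mean(col)  # the passband excludes DC; removing it up front
                            # keeps forward-backward edge transients small
    if (spec$zero_phase) filtfilt(bf, col) else as.numeric(signal::filter(bf, col))
  })
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Integrate angular rate to angular displacement
#'
#' Cumulative trapezoidal integration per axis, starting at zero. Applied to
#' band-passed angular rate this yields an implicitly detrended (bounded)
#' sway displacement.
#'
#' @param w Angular rate vector or n x k matrix, rad/s.
#' @param fs Sampling rate, Hz.
#' @return Angular displacement, same shape, rad.
#' @export
integrate_gyro <- function(w, fs) {
  if (is.null(dim(w))) as.numeric(cumtrapz_fs(cbind(w), fs)) else cumtrapz_fs(w, fs)
}

#' Align and filter one placement's signals
#'
#' Convenience wrapper running the full per-placement preprocessing chain:
#' gravity axis from the static lead-in, frontal axis by PCA over walking,
#' rotation into the body frame, band-pass of the walking segment, and
#' integration of the filtered angular rates to pitch/roll displacement.
#'
#' @param acc,gyr Raw n x 3 sensor-frame matrices for the whole trial.
#' @param fs Sampling rate, Hz.
#' @param static_lead_in Length of the quiet-standing lead-in, s.
#' @param spec A [filter_spec()].
#' @return List: `axes`, full-trial aligned `acc`/`gyr`, band-passed walking
#'   segment `acc_f`/`gyr_f`, angular displacement `theta` (columns x = roll,
#'   y = pitch) and the walking-sample index `walk_idx`.
#' @export
preprocess_signals <- function(acc, gyr, fs, static_lead_in = 2,
                               spec = filter_spec()) {
  n <- nrow(acc)
  n_static <- round(static_lead_in * fs)
  if (n_static < round(0.5 * fs)) {
    abort("Static lead-in must cover at least 0.5 s.",
          class = "vestigait_error_no_static_gravity")
  }
  walk_idx <- (n_static + 1):n
  z <- estimate_gravity_axis(acc[seq_len(n_static), , drop = FALSE])
  axes <- estimate_frontal_axis(gyr[walk_idx, , drop = FALSE], z)
  aligned <- align_axes(acc, gyr, axes)
  acc_f <- bandpass(aligned$acc[walk_idx, , drop = FALSE], spec, fs)
  gyr_f <- bandpass(aligned$gyr[walk_idx, , drop = FALSE], spec, fs)
  theta <- integrate_gyro(gyr_f[, 1:2, drop = FALSE], fs)
  colnames(theta) <- c("x", "y")
  list(axes = axes, acc = aligned$acc, gyr = aligned$gyr,
       acc_f = acc_f, gyr_f = gyr_f, theta = theta, walk_idx = walk_idx)
}
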