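test_that("gravity axis estimation handles constructed orientations", {
  n <- 128
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  expect_equal(estimate_gravity_axis(acc), c(0, 0, 1))

  tilted <- matrix(rep(9.81 * c(0, sin(10 * pi / 180), cos(10 * pi / 180)),
                       each = n), n, 3)
  z <- estimate_gravity_axis(tilted)
  expect_unit(z)
  expect_equal(vestigait:::angle_deg(z, c(0, 0, 1)), 10, tolerance = 1e-6)

  # moving sensor: mean acceleration well below g
  moving <- matrix(rnorm(n * 3, 0, 1), n, 3)
  expect_error(estimate_gravity_axis(moving),
               class = "vestigait_error_no_static_gravity")
})

test_that("alignment recovers random mounting rotations", {
  cfg0 <- noise_free_config(mounting_rotation_sd = 0.25)
  cfg1 <- sim_config(n_per_class = 1, tasks = "GEC", trials_per_task = 1,
                     arm_pitch_range_sd = c(0, 0), mounting_rotation_sd = 0.25)
  err0 <- err1 <- erry <- numeric(100)
  for (i in 1:100) {
    s0 <- simulate_trial(cfg0, "C01", "GEC", seed = i, placements = "left_arm")
    s1 <- simulate_trial(cfg1, "C01", "GEC", seed = i, placements = "left_arm")
    n_static <- round(cfg0$static_lead_in * cfg0$fs)
    for (j in 1:2) {
      s <- list(s0, s1)[[j]]
      R <- s$truth$mounting$left_arm
      zh <- estimate_gravity_axis(
        s$recording$placements$left_arm$acc[seq_len(n_static), ])
      e <- vestigait:::angle_deg(zh, t(R) %*% c(0, 0, 1))
      if (j == 1) err0[i] <- e else err1[i] <- e
    }
    axes <- estimate_frontal_axis(
      s1$recording$placements$left_arm$gyr[-seq_len(n_static), ],
      estimate_gravity_axis(s1$recording$placements$left_arm$acc[seq_len(n_static), ]))
    erry[i] <- vestigait:::angle_deg(axes$y, t(s1$truth$mounting$left_arm) %*% c(0, 1, 0),
                                     axis = TRUE)
  }
  expect_lt(max(err0), 0.1)   # noise-free
  expect_lt(max(err1), 2)     # default sensor noise
  expect_lt(max(erry), 5)     # frontal axis from the arm swing
})

test_that("frontal-axis PCA matches the covariance eigenvector oracle", {
  set.seed(4)
  z <- c(0, 0, 1)
  t <- seq(0, 10, by = 1 / 128)
  u <- c(1, 0, 0); v <- c(0, 1, 0)
  # dominant rotation about u, weaker about v at another frequency (5:1)
  gyro <- outer(5 * sin(2 * pi * 1.0 * t), u) + outer(1 * sin(2 * pi * 2.3 * t), v)
  axes <- estimate_frontal_axis(gyro, z)
  # oracle: eigenvector of the analytic projected covariance diag(25/2, 1/2)
  expect_lt(vestigait:::angle_deg(axes$y, u, axis = TRUE), 1)
  expect_unit(axes$x); expect_unit(axes$y); expect_unit(axes$z)
  expect_lt(abs(sum(axes$x * axes$y)), 1e-8)
  expect_lt(abs(sum(axes$y * axes$z)), 1e-8)
  expect_gt(sum(axes$x * vestigait:::cross3(axes$y, axes$z)), 0)  # right-handed

  # rank-1 rotation about a single in-plane axis
  g1 <- outer(sin(2 * pi * t), unit_v <- c(sqrt(0.5), sqrt(0.5), 0))
  axes1 <- estimate_frontal_axis(g1, z)
  expect_lt(vestigait:::angle_deg(axes1$y, unit_v, axis = TRUE), 1e-6)

  # isotropic in-plane rotation: ambiguous
  giso <- cbind(rnorm(20000), rnorm(20000), rnorm(20000))
  expect_error(estimate_frontal_axis(giso, z),
               class = "vestigait_error_ambiguous_axes")
})

test_that("align_axes is a pure rotation", {
  set.seed(5)
  acc <- matrix(rnorm(300), 100, 3)
  gyr <- matrix(rnorm(300), 100, 3)
  ident <- structure(list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1)),
                     class = "body_frame_axes")
  out <- align_axes(acc, gyr, ident)
  expect_equal(unname(out$acc), acc)
  R <- vestigait:::rotvec_to_matrix(c(0.2, -0.1, 0.3))
  axes <- structure(list(x = R[1, ], y = R[2, ], z = R[3, ]),
                    class = "body_frame_axes")
  rot <- align_axes(acc, gyr, axes)
  expect_lt(max(abs(vestigait:::row_norms(rot$acc) - vestigait:::row_norms(acc))), 1e-10)
  expect_lt(max(abs(vestigait:::row_norms(rot$gyr) - vestigait:::row_norms(gyr))), 1e-10)
})

test_that("band-pass keeps gait frequencies and rejects DC and high frequency", {
  fs <- 128
  t <- (0:(20 * fs - 1)) / fs
  spec <- filter_spec()
  mid <- (5 * fs):(15 * fs)

  const <- bandpass(rep(3, length(t)), spec, fs)
  expect_lt(max(abs(const[mid])), 1e-6 * 3)

  s2 <- bandpass(sin(2 * pi * 2 * t), spec, fs)
  amp <- max(abs(s2[mid]))
  expect_gte(amp, 0.95); expect_lte(amp, 1.05)
  # zero phase: peaks stay on the 2 Hz grid (period 64 samples)
  peak <- which.max(s2[mid])
  ref <- which.max(sin(2 * pi * 2 * t[mid]))
  expect_lte(min((peak - ref) %% 64, (ref - peak) %% 64), 1)

  s50 <- bandpass(sin(2 * pi * 50 * t), spec, fs)
  expect_lt(max(abs(s50[mid])), 0.1)

  # passband idempotence
  twice <- bandpass(s2, spec, fs)
  expect_lt(abs(max(abs(twice[mid])) - amp) / amp, 0.01)

  expect_error(bandpass(rnorm(20), spec, fs),
               class = "vestigait_error_filter_length")
  expect_error(filter_spec(low = 30, high = 25),
               class = "vestigait_error_invalid_config")
})

test_that("gyro integration matches closed forms", {
  fs <- 128
  th <- integrate_gyro(rep(0.1, 2 * fs + 1), fs)
  expect_equal(th[1], 0)
  expect_equal(th[length(th)], 0.2, tolerance = 1e-10)

  t <- (0:(10 * fs - 1)) / fs
  A <- 0.8; f <- 1.2
  th2 <- integrate_gyro(A * sin(2 * pi * f * t), fs)
  expect_equal(diff(range(th2)), 2 * A / (2 * pi * f), tolerance = 0.01)

  expect_equal(integrate_gyro(numeric(50), fs), numeric(50))
})
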