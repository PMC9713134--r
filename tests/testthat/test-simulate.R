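test_that("cohort layout matches the emulated protocol", {
  cfg <- sim_config(n_per_class = 2, tasks = c("GEC", "SSGS"),
                    trials_per_task = 2, seed = 3)
  co <- simulate_cohort(cfg, placements = "head")
  expect_length(co$trials, 2 * 2 * 2 * 2)  # participants x tasks x trials
  expect_equal(nrow(co$manifest), length(co$trials))
  expect_equal(sum(co$manifest$label == 1), sum(co$manifest$label == 0))

  # one task at the default cohort size: 30 participants x 3 trials = 90
  cfg90 <- sim_config(tasks = "GEC", seed = 3)
  co90 <- simulate_cohort(cfg90, placements = "head")
  expect_length(co90$trials, 90)
  expect_equal(length(unique(co90$manifest$participant_id)), 30)
})

test_that("identical config and seed reproduce the cohort bit-identically", {
  cfg <- sim_config(n_per_class = 2, tasks = "GEC", trials_per_task = 1,
                    seed = 11)
  a <- simulate_cohort(cfg, placements = c("left_arm", "left_foot"))
  b <- simulate_cohort(cfg, placements = c("left_arm", "left_foot"))
  expect_identical(a$trials, b$trials)
  expect_identical(a$truths, b$truths)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(trial_duration = -1),
               class = "vestigait_error_invalid_config")
  expect_error(sim_config(fs = 128, trial_duration = 1.0001),
               class = "vestigait_error_invalid_config")
  expect_error(sim_config(tasks = "WALK"),
               class = "vestigait_error_invalid_config")
  cfg <- sim_config()
  expect_error(simulate_trial(cfg, "C01", "NOPE"),
               class = "vestigait_error_invalid_config")
})

test_that("noise-free construction yields exact stride ground truth", {
  cfg <- noise_free_config(stride_length = 1.2)
  s <- simulate_trial(cfg, "C01", "GEC", seed = 1)
  for (foot in c("left_foot", "right_foot")) {
    expect_true(all(s$truth$feet[[foot]]$stride_lengths == 1.2))
  }
  # stride counts per foot differ by at most one
  nL <- length(s$truth$feet$left_foot$stride_lengths)
  nR <- length(s$truth$feet$right_foot$stride_lengths)
  expect_lte(abs(nL - nR), 1)
  # stance honesty: ground-truth foot speed is exactly zero in every stance
  t <- (seq_len(nrow(s$truth$feet$left_foot$velocity)) - 1) / cfg$fs
  iv <- s$truth$feet$left_foot$stationary_intervals
  for (k in seq_len(nrow(iv))) {
    inside <- t >= iv[k, 1] & t <= iv[k, 2]
    expect_true(all(s$truth$feet$left_foot$velocity[inside, ] == 0))
  }
})

test_that("mounting rotations are orthonormal and recoverable", {
  cfg <- sim_config(n_per_class = 1, tasks = "GEC", trials_per_task = 1,
                    mounting_rotation_sd = 0.3)
  s <- simulate_trial(cfg, "V01", "GEC", seed = 5)
  for (R in s$truth$mounting) {
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
  }
})

test_that("double-integrated noise-free foot acceleration matches stride displacement", {
  cfg <- noise_free_config(stride_length = 1.2)
  s <- simulate_trial(cfg, "C01", "GEC", seed = 2)
  acc <- s$recording$placements$left_foot$acc
  fs <- cfg$fs
  # independent oracle: trapezoidal double integration of the recorded
  # forward acceleration (identity mounting, gravity confined to z)
  vx <- pracma::cumtrapz(seq_len(nrow(acc)), acc[, 1])[, 1] / fs
  px <- pracma::cumtrapz(seq_len(nrow(acc)), vx)[, 1] / fs
  anchors <- round(s$truth$feet$left_foot$footfall_times * fs) + 1
  disp <- diff(px[anchors])
  # tolerance covers the sample-grid discretization of the swing boundaries
  expect_equal(disp, rep(1.2, length(disp)), tolerance = 0.01)
})

test_that("static lead-in measures gravity through the mounting rotation", {
  cfg <- sim_config(n_per_class = 1, tasks = "GEC", trials_per_task = 1,
                    mounting_rotation_sd = 0.2, seed = 1)
  s <- simulate_trial(cfg, "C01", "GEC", seed = 9)
  n_static <- round(cfg$static_lead_in * cfg$fs)
  for (p in c("head", "left_foot", "right_wrist")) {
    m <- colMeans(s$recording$placements[[p]]$acc[seq_len(n_static), ])
    rotated <- s$truth$mounting[[p]] %*% m
    tol <- 3 * cfg$accel_noise_sd / sqrt(n_static)
    expect_lt(max(abs(rotated - c(0, 0, 9.81))), 3 * tol)
  }
})

test_that("arm pitch contrast matches the study population parameters", {
  cfg <- sim_config(tasks = "GEC", seed = 17)
  co <- simulate_cohort(cfg, placements = "head")
  arm <- sapply(co$truths, function(tt) tt$arm_pitch_range[["left"]])
  lab <- sapply(co$truths, function(tt) tt$label)
  m_v <- mean(arm[lab == 1])
  m_c <- mean(arm[lab == 0])
  expect_equal(m_v, 0.26, tolerance = 0.07 / 0.26)   # ~3 SE of the cohort mean
  expect_equal(m_c - m_v, 0.49 - 0.26, tolerance = 0.12 / 0.23)
  # eyes-closed contrast exceeds the self-selected-speed contrast
  cfg2 <- sim_config(tasks = c("GEC", "SSGS"), seed = 18)
  co2 <- simulate_cohort(cfg2, placements = "head")
  arm2 <- sapply(co2$truths, function(tt) tt$arm_pitch_range[["left"]])
  lab2 <- sapply(co2$truths, function(tt) tt$label)
  task2 <- sapply(co2$truths, function(tt) tt$task_id)
  gap_gec <- mean(arm2[lab2 == 0 & task2 == "GEC"]) - mean(arm2[lab2 == 1 & task2 == "GEC"])
  gap_ssgs <- mean(arm2[lab2 == 0 & task2 == "SSGS"]) - mean(arm2[lab2 == 1 & task2 == "SSGS"])
  expect_gt(gap_gec, gap_ssgs)
})

test_that("cohort round-trips through the directory format bit-exactly", {
  co <- small_cohort(n_per_class = 1, trials = 1,
                     placements = c("left_arm", "left_foot"), seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$trials), length(co$trials))
  for (i in seq_along(co$trials)) {
    for (p in names(co$trials[[i]]$placements)) {
      expect_identical(unname(back$trials[[i]]$placements[[p]]$acc),
                       unname(co$trials[[i]]$placements[[p]]$acc))
      expect_identical(unname(back$trials[[i]]$placements[[p]]$gyr),
                       unname(co$trials[[i]]$placements[[p]]$gyr))
    }
    expect_equal(back$truths[[i]]$feet$left_foot$stride_lengths,
                 co$truths[[i]]$feet$left_foot$stride_lengths)
    expect_equal(unname(back$truths[[i]]$mounting$left_arm),
                 unname(co$truths[[i]]$mounting$left_arm))
  }
  expect_equal(back$manifest$label, co$manifest$label)
})
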