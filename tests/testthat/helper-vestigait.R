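# shared fixtures, all built in code

# deterministic kinematics: no sensor noise, no mounting rotation, no
# stochastic stride/arm variation, degenerate class parameters
noise_free_config <- function(stride_length = 1.2, stride_time = 1.1,
                              mounting_rotation_sd = 0, ...) {
  sim_config(
    n_per_class = 1, tasks = "GEC", trials_per_task = 1,
    stride_length_mean = c(control = stride_length, vestibular = stride_length),
    stride_time_mean = c(control = stride_time, vestibular = stride_time),
    stride_length_sd = 0, stride_time_sd = 0, stride_length_cv = 0,
    arm_pitch_range_sd = c(control = 0, vestibular = 0),
    accel_noise_sd = 0, gyro_noise_sd = 0, gyro_bias_drift = 0,
    mounting_rotation_sd = mounting_rotation_sd, ...
  )
}

# small noisy cohort for pipeline-level tests
small_cohort <- function(n_per_class = 4, tasks = "GEC", trials = 2,
                         placements = "left_arm", seed = 42) {
  cfg <- sim_config(n_per_class = n_per_class, tasks = tasks,
                    trials_per_task = trials, seed = seed)
  simulate_cohort(cfg, placements = placements)
}

# a perfectly separable synthetic feature dataset with grouped participants
separable_dataset <- function(n_per_class = 8, trials = 3, p = 6, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("V%02d", 1:n_per_class), sprintf("C%02d", 1:n_per_class))
  rows <- lapply(ids, function(id) {
    lab <- as.integer(startsWith(id, "V"))
    f <- matrix(rnorm(trials * p, mean = 3 * lab, sd = 0.1), trials, p)
    colnames(f) <- sprintf("f%02d", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(participant_id = id, task_id = "GEC",
                     trial_index = seq_len(trials), label = lab),
      tibble::as_tibble(f)
    )
  })
  purrr::list_rbind(rows)
}

# pure-noise features: labels independent of everything
noise_dataset <- function(n_per_class = 8, trials = 3, p = 6, seed = 1) {
  ds <- separable_dataset(n_per_class, trials, p, seed)
  ds[sprintf("f%02d", seq_len(p))] <-
    matrix(rnorm(nrow(ds) * p), nrow(ds), p)
  ds
}

expect_unit <- function(v, tol = 1e-8) {
  expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
}
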