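test_that("split plans hold out 3+3 participants with zero leakage", {
  ids <- c(sprintf("V%02d", 1:15), sprintf("C%02d", 1:15))
  labels <- rep(c(1, 0), each = 15)
  plan <- make_split_plan(ids, labels, n_repeats = 50, seed = 2)
  expect_equal(nrow(plan), 50)
  for (i in seq_len(nrow(plan))) {
    expect_length(plan$test[[i]], 6)
    expect_length(plan$train[[i]], 24)
    expect_length(intersect(plan$test[[i]], plan$train[[i]]), 0)
    test_labels <- as.integer(startsWith(plan$test[[i]], "V"))
    expect_equal(sum(test_labels), 3)
  }
  expect_identical(plan, make_split_plan(ids, labels, n_repeats = 50, seed = 2))
  expect_error(make_split_plan(c("V01", "V02", "C01", "C02", "C03"),
                               c(1, 1, 0, 0, 0), seed = 1),
               class = "vestigait_error_invalid_cohort")
})

test_that("standardization uses training statistics only", {
  sc <- standardize(matrix(c(1, 2, 3), ncol = 1), matrix(2, ncol = 1))
  expect_equal(as.numeric(sc$train), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(as.numeric(sc$test), 0)  # test value at the train mean

  # constant training feature maps to zero on both sides
  sc2 <- standardize(matrix(5, 4, 1), matrix(c(7, 9), 2, 1))
  expect_true(all(sc2$train == 0) && all(sc2$test == 0))

  # perturbing test rows never touches the scaler
  set.seed(3)
  tr <- matrix(rnorm(40), 10, 4)
  a <- standardize(tr, matrix(rnorm(20), 5, 4))
  b <- standardize(tr, matrix(rnorm(20, 100), 5, 4))
  expect_identical(a$center, b$center)
  expect_identical(a$scale, b$scale)
  expect_error(standardize(matrix(numeric(0), 0, 2)),
               class = "vestigait_error_empty_input")
})

test_that("AUROC follows the midrank convention and matches pROC", {
  labels <- c(0, 0, 1, 1)
  expect_equal(auroc(labels, c(0, 0, 1, 1)), 1)
  expect_equal(auroc(labels, rep(0.5, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)),
               class = "vestigait_error_undefined_auroc")
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(auroc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("group k-fold tuning behaves on separable and null data", {
  ds <- separable_dataset(n_per_class = 6, trials = 2, p = 5, seed = 5)
  x <- as.matrix(ds[, sprintf("f%02d", 1:5)])
  cfg2 <- model_config(num_trees = c(100, 200), max_features = "sqrt",
                       max_depth = 0, min_node_size = 1, k = 4, seed = 6)
  fit <- tune_and_train(x, ds$label, ds$participant_id, cfg2)
  expect_equal(fit$cv_auroc, 1.0)
  expect_equal(nrow(fit$grid_results), 2)

  # grid of size one skips tuning and returns that configuration
  cfg1 <- model_config(num_trees = 150, max_features = "0.3", max_depth = 5,
                       min_node_size = 2, seed = 6)
  fit1 <- tune_and_train(x, ds$label, ds$participant_id, cfg1)
  expect_equal(fit1$best_params$num_trees, 150)
  expect_true(is.na(fit1$cv_auroc))

  # label-feature independence: winner's inner-CV AUROC near chance
  nd <- noise_dataset(n_per_class = 8, trials = 3, p = 5, seed = 7)
  fitn <- tune_and_train(as.matrix(nd[, sprintf("f%02d", 1:5)]),
                         nd$label, nd$participant_id, cfg2)
  expect_gt(fitn$cv_auroc, 0.3)
  expect_lt(fitn$cv_auroc, 0.7)
})

test_that("merged evaluation pools held-out predictions correctly", {
  ds <- separable_dataset(n_per_class = 5, trials = 3, p = 4, seed = 8)
  pp <- dplyr::distinct(ds, participant_id, label)
  plan <- make_split_plan(pp$participant_id, pp$label, n_repeats = 12,
                          n_test_per_class = 1, seed = 9)
  ev <- evaluate(ds, plan, fast_model_config(n_boot = 200, seed = 9))
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$metrics$accuracy, 1.0)
  expect_equal(sum(ev$confusion), nrow(ev$predictions))
  expect_true(ev$ci[1] <= ev$auroc && ev$auroc <= ev$ci[2])
  g <- glance(ev)
  expect_equal(g$auroc, 1.0)
  expect_equal(nrow(tidy(ev)), nrow(ev$predictions))
})

test_that("a wider arm-swing gap never lowers the eyes-closed AUROC", {
  aurocs <- sapply(c(0.49, 0.375, 0.26), function(vest_mean) {
    cfg <- sim_config(n_per_class = 8, tasks = "GEC", trials_per_task = 2,
                      arm_pitch_range = c(control = 0.49, vestibular = vest_mean),
                      seed = 40)
    co <- simulate_cohort(cfg, placements = "left_arm")
    feats <- extract_cohort_features(co, feature_spec("left_arm"))
    ds <- build_dataset(feats, "GEC")
    pp <- dplyr::distinct(ds, participant_id, label)
    plan <- make_split_plan(pp$participant_id, pp$label, n_repeats = 15,
                            seed = 41)
    evaluate(ds, plan, fast_model_config(n_boot = 50, seed = 42))$auroc
  })
  expect_true(all(diff(aurocs) >= 0))
})

test_that("the placement x task grid evaluates every requested cell", {
  co <- small_cohort(n_per_class = 4, tasks = c("GEC", "SSGS"), trials = 2,
                     placements = c("left_arm", "head"), seed = 44)
  feats <- extract_cohort_features(co, feature_spec(c("left_arm", "head")))
  grid <- placement_task_grid(feats, c("left_arm", "head"), c("GEC", "SSGS"),
                              fast_model_config(n_boot = 50, seed = 45),
                              n_repeats = 8)
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$auroc >= 0 & grid$auroc <= 1))
  m <- grid_margins(grid)
  expect_equal(m$by_placement$mean_auroc[m$by_placement$placement == "left_arm"],
               mean(grid$auroc[grid$placement == "left_arm"]))
  expect_equal(nrow(tidy(grid)), 4)
})
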