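# subject-wise repeated Random-Forest evaluation with merged-prediction AUROC

#' Random-Forest model configuration
#'
#' Hyperparameter grid (number of trees, maximum features per split,
#' maximum depth, minimum node size), tuned by group k-fold cross-validation
#' on the training split, optimizing AUROC; ties broken by grid order.
#' `max_depth = 0` means unbounded; `max_features` entries are `"sqrt"` or a
#' fraction of the feature count.
#'
#' @param num_trees,max_features,max_depth,min_node_size Grid values.
#' @param k Inner group-CV folds (grouped by participant).
#' @param n_boot Bootstrap resamples for the merged-AUROC CI.
#' @param seed Seed for tuning folds, forests and the bootstrap.
#' @return A `model_config` with the expanded `grid`.
#' @export
model_config <- function(num_trees = c(100, 300, 500),
                         max_features = c("sqrt", "0.1", "0.3"),
                         max_depth = c(0, 5, 10),
                         min_node_size = c(1, 2, 5),
                         k = 5, n_boot = 1000, seed = 1L) {
  grid <- expand.grid(num_trees = num_trees,
                      max_features = as.character(max_features),
                      max_depth = max_depth,
                      min_node_size = min_node_size,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) {
    abort("Hyperparameter grid is empty.", class = "vestigait_error_invalid_config")
  }
  structure(list(grid = as_tibble(grid), k = k, n_boot = n_boot,
                 seed = as.integer(seed)), class = "model_config")
}

#' Single-point model configuration
#'
#' Skips inner tuning: one forest of 500 trees, sqrt features, unbounded
#' depth, node size 1. Useful when the tuning grid is not the object of
#' study.
#'
#' @inheritParams model_config
#' @export
fast_model_config <- function(n_boot = 1000, seed = 1L) {
  model_config(num_trees = 500, max_features = "sqrt", max_depth = 0,
               min_node_size = 1, n_boot = n_boot, seed = seed)
}

#' Subject-wise repeated split plan
#'
#' Each repeat holds out 3 participants per class for testing (6 of 30 under
#' the default cohort, an 80/20 split) and trains on the rest. All trials of
#' a participant stay on one side, eliminating identity leakage. Repeats are
#' drawn independently, so participants may recur across test sets.
#'
#' @param participants Participant IDs (one entry per participant).
#' @param labels Binary label per participant.
#' @param n_repeats Number of repeated splits.
#' @param n_test_per_class Held-out participants per class per repeat.
#' @param seed Seed for the draws.
#' @return A `split_plan` tibble: `repeat_id`, list-columns `test`, `train`.
#' @export
make_split_plan <- function(participants, labels, n_repeats = 50,
                            n_test_per_class = 3, seed = 1L) {
  stopifnot(length(participants) == length(labels))
  dup <- duplicated(participants)
  participants <- participants[!dup]
  labels <- as.integer(labels[!dup])
  by_class <- split(participants, labels)
  if (length(by_class) < 2L || any(lengths(by_class) < n_test_per_class)) {
    abort(sprintf("Need >= %d participants per class.", n_test_per_class),
          class = "vestigait_error_invalid_cohort")
  }
  set.seed(seed)
  plan <- map(seq_len(n_repeats), function(i) {
    held_out <- c(sample(by_class[["0"]], n_test_per_class),
                  sample(by_class[["1"]], n_test_per_class))
    kept <- setdiff(participants, held_out)
    tibble(repeat_id = i, test = list(held_out), train = list(kept))
  }) |> list_rbind()
  class(plan) <- c("split_plan", class(plan))
  plan
}

#' Standardize features using training statistics only
#'
#' Per-feature mean and SD are computed on the training matrix and applied
#' to both matrices; zero-variance training features are mapped to 0 on both
#' sides. Test data never influence the scaler.
#'
#' @param train,test Numeric matrices / data frames (test may be `NULL`).
#' @return List: `train`, `test`, `center`, `scale` (NA where degenerate).
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) {
    abort("Training matrix is empty.", class = "vestigait_error_empty_input")
  }
  center <- colMeans(train)
  # population SD (divide by n), matching the usual ML scaler convention
  scale_ <- sqrt(colMeans(sweep(train, 2, center, "-")^2))
  dead <- !is.finite(scale_) | scale_ < 1e-12
  apply_scale <- function(m) {
    m <- as.matrix(m)
    out <- sweep(sweep(m, 2, center, "-"), 2, ifelse(dead, 1, scale_), "/")
    out[, dead] <- 0
    out
  }
  list(train = apply_scale(train),
       test = if (!is.null(test)) apply_scale(test) else NULL,
       center = center, scale = ifelse(dead, NA_real_, scale_))
}

resolve_mtry <- function(max_features, p) {
  if (max_features == "sqrt") return(max(1L, floor(sqrt(p))))
  frac <- suppressWarnings(as.numeric(max_features))
  if (!is.finite(frac) || frac <= 0 || frac > 1) {
    abort(sprintf("Invalid max_features '%s'.", max_features),
          class = "vestigait_error_invalid_config")
  }
  max(1L, floor(frac * p))
}

fit_rf <- function(x, y, params, seed) {
  ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
         probability = TRUE,
         num.trees = params$num_trees,
         mtry = resolve_mtry(params$max_features, ncol(x)),
         max.depth = params$max_depth,
         min.node.size = params$min_node_size,
         seed = seed, num.threads = 1)
}

predict_prob <- function(model, x) {
  predict(model, data = as.data.frame(x), num.threads = 1)$predictions[, "1"]
}

#' Tune hyperparameters by group k-fold and fit the final forest
#'
#' For each grid point, inner folds group by participant; the point with the
#' best mean validation AUROC wins (ties to the earlier grid row) and is
#' refit on the full training split. Inner folds containing one class are
#' skipped with a warning. A size-1 grid skips the inner loop entirely.
#'
#' @param x Training feature matrix (already standardized).
#' @param y Binary labels.
#' @param groups Participant ID per row.
#' @param config A [model_config()].
#' @return An `rf_fit`: `model`, `best_params`, `cv_auroc`, `grid_results`.
#' @export
tune_and_train <- function(x, y, groups, config = fast_model_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  grid <- config$grid
  if (nrow(grid) == 1L) {
    model <- fit_rf(x, y, grid[1, ], config$seed)
    return(structure(list(model = model, best_params = grid[1, ],
                          cv_auroc = NA_real_, grid_results = NULL),
                     class = "rf_fit"))
  }
  ids <- unique(groups)
  if (length(ids) < config$k) {
    abort(sprintf("Need >= %d participant groups for %d-fold tuning.",
                  config$k, config$k),
          class = "vestigait_error_invalid_cohort")
  }
  set.seed(config$seed)
  fold_of <- setNames(rep_len(seq_len(config$k), length(ids)), sample(ids))
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    fold_auc <- rep(NA_real_, config$k)
    for (f in seq_len(config$k)) {
      hold <- groups %in% names(fold_of)[fold_of == f]
      if (length(unique(y[hold])) < 2L) {
        warn(sprintf("Inner fold %d has one class; skipped.", f))
        next
      }
      m <- fit_rf(x[!hold, , drop = FALSE], y[!hold], grid[gi, ], config$seed + f)
      fold_auc[f] <- auroc(y[hold], predict_prob(m, x[hold, , drop = FALSE]))
    }
    scores[gi] <- mean(fold_auc, na.rm = TRUE)
  }
  best <- which.max(scores)
  model <- fit_rf(x, y, grid[best, ], config$seed)
  structure(list(model = model, best_params = grid[best, ],
                 cv_auroc = scores[best],
                 grid_results = bind_cols(grid, cv_auroc = scores)),
            class = "rf_fit")
}

threshold_metrics <- function(labels, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  fp <- sum(pred == 1 & labels == 0); tn <- sum(pred == 0 & labels == 0)
  confusion <- matrix(c(tn, fp, fn, tp), nrow = 2, byrow = TRUE,
                      dimnames = list(true = c("0", "1"),
                                      predicted = c("0", "1")))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- tp / (tp + fn)
  tibble(accuracy = (tp + tn) / length(labels),
         f1 = if (is.na(precision) || precision + sensitivity == 0) 0 else
           2 * precision * sensitivity / (precision + sensitivity),
         sensitivity = sensitivity,
         specificity = tn / (tn + fp)) |>
    list(confusion = confusion, metrics = _)
}

#' Evaluate a dataset under a subject-wise split plan
#'
#' For every repeat: standardize on the training split only, tune and train
#' the forest, predict held-out probabilities. All held-out (label,
#' probability) pairs are pooled into one merged test set; performance is
#' the AUROC of that pool with a percentile bootstrap CI, plus threshold-0.5
#' accuracy, F1, sensitivity, specificity and the 2 x 2 confusion matrix.
#'
#' @param dataset A task dataset tibble from [build_dataset()].
#' @param plan A `split_plan` over the dataset's participants.
#' @param config A [model_config()].
#' @param feature_cols Feature columns to use (default: all non-metadata
#'   columns; pass a placement's columns for single-IMU models).
#' @return A `gait_eval`: merged `predictions` tibble, `auroc`, `ci`,
#'   `metrics`, `confusion`.
#' @export
evaluate <- function(dataset, plan, config = fast_model_config(),
                     feature_cols = NULL) {
  feature_cols <- feature_cols %||% feature_columns(dataset)
  x_all <- as.matrix(dataset[, feature_cols, drop = FALSE])
  preds <- map(seq_len(nrow(plan)), function(i) {
    test_ids <- plan$test[[i]]
    train_ids <- plan$train[[i]]
    stopifnot(length(intersect(test_ids, train_ids)) == 0L)
    tr <- dataset$participant_id %in% train_ids
    te <- dataset$participant_id %in% test_ids
    sc <- standardize(x_all[tr, , drop = FALSE], x_all[te, , drop = FALSE])
    fit <- tune_and_train(sc$train, dataset$label[tr],
                          dataset$participant_id[tr], config)
    tibble(repeat_id = i,
           participant_id = dataset$participant_id[te],
           trial_index = dataset$trial_index[te],
           label = dataset$label[te],
           prob = predict_prob(fit$model, sc$test))
  }) |> list_rbind()
  if (length(unique(preds$label)) < 2L) {
    abort("Pooled predictions contain a single class; AUROC undefined.",
          class = "vestigait_error_undefined_auroc")
  }
  point <- auroc(preds$label, preds$prob)
  set.seed(config$seed)
  n <- nrow(preds)
  boots <- map_dbl(seq_len(config$n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(preds$label[idx])) < 2L) return(NA_real_)
    auroc(preds$label[idx], preds$prob[idx])
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  thr <- threshold_metrics(preds$label, preds$prob)
  structure(list(predictions = preds, auroc = point, ci = ci,
                 metrics = thr$metrics, confusion = thr$confusion,
                 n_repeats = nrow(plan),
                 task_id = attr(dataset, "task_id")),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat(sprintf("<gait_eval> merged AUROC %.3f [%.3f, %.3f] over %d repeats (%d pooled predictions)\n",
              x$auroc, x$ci[1], x$ci[2], x$n_repeats, nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' Evaluate the placement x task model grid
#'
#' Trains one single-IMU model per (placement, task) cell, mirroring the
#' "one IMU at a time, one task at a time" experiment grid, and reports the
#' merged AUROC per cell.
#'
#' @param features Cohort feature tibble covering the requested placements
#'   and tasks.
#' @param placements,tasks Grid axes.
#' @param config A [model_config()].
#' @param plan Optional shared `split_plan`; built from the cohort's
#'   participants with `config$seed` when `NULL`.
#' @param n_repeats Repeats for the default plan.
#' @return A `gait_grid` tibble: placement, task, auroc, ci bounds and a
#'   list-column of the full `gait_eval` objects.
#' @export
placement_task_grid <- function(features, placements, tasks,
                                config = fast_model_config(), plan = NULL,
                                n_repeats = 50) {
  stopifnot(all(placements %in% vestigait_placements()))
  if (is.null(plan)) {
    pp <- features |> distinct(.data$participant_id, .data$label)
    plan <- make_split_plan(pp$participant_id, pp$label,
                            n_repeats = n_repeats, seed = config$seed)
  }
  cells <- tidyr::expand_grid(placement = placements, task = tasks)
  evals <- map(seq_len(nrow(cells)), function(i) {
    ds <- build_dataset(features, cells$task[i])
    evaluate(ds, plan, config,
             feature_cols = feature_columns(ds, cells$placement[i]))
  })
  out <- cells |>
    mutate(auroc = map_dbl(evals, "auroc"),
           ci_lo = map_dbl(evals, ~ .x$ci[1]),
           ci_hi = map_dbl(evals, ~ .x$ci[2]),
           eval = evals)
  class(out) <- c("gait_grid", class(out))
  out
}

#' Row/column means of a model grid
#'
#' Average AUROC per placement (across tasks) and per task (across
#' placements) -- the grid margins.
#'
#' @param grid A `gait_grid`.
#' @return List of two tibbles: `by_placement`, `by_task`.
#' @export
grid_margins <- function(grid) {
  list(
    by_placement = grid |> summarize(mean_auroc = mean(.data$auroc),
                                     .by = "placement"),
    by_task = grid |> summarize(mean_auroc = mean(.data$auroc), .by = "task")
  )
}
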