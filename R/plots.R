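# ggplot2 visualizations of result objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve of the merged held-out predictions
#'
#' @param object A `gait_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_eval <- function(object, ...) {
  pts <- roc_points(object$predictions$label, object$predictions$prob)
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                color = "grey60") +
    geom_step(linewidth = 0.8, color = "#2166AC") +
    coord_equal() +
    labs(x = "False positive rate (1 - specificity)",
         y = "True positive rate (sensitivity)",
         title = sprintf("Merged-prediction ROC, AUROC = %.2f [%.2f, %.2f]",
                         object$auroc, object$ci[1], object$ci[2])) +
    theme_minimal()
}

#' Heatmap of the placement x task AUROC grid
#'
#' @param object A `gait_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gait_grid <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$task, y = .data$placement, fill = .data$auroc)) +
    geom_tile(color = "white") +
    geom_text(aes(label = sprintf("%.2f", .data$auroc)), size = 3) +
    scale_fill_gradient2(low = "#B2182B", mid = "white", high = "#2166AC",
                         midpoint = 0.5, limits = c(0, 1)) +
    labs(x = "Gait task", y = "IMU placement", fill = "AUROC") +
    theme_minimal()
}

#' Cluster permutation importance with CI bars
#'
#' @param object A `cluster_importance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_importance <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(cluster = factor(.data$cluster))
  ggplot(d, aes(x = stats::reorder(.data$cluster, -.data$mean_drop),
                y = .data$mean_drop)) +
    geom_col(fill = "#2166AC", width = 0.6) +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.2) +
    labs(x = "Feature cluster", y = "AUROC drop when permuted") +
    theme_minimal()
}

#' Dendrogram of the feature-correlation clustering
#'
#' @param x A `feature_clusters`.
#' @param ... Passed to [plot()].
#' @export
plot.feature_clusters <- function(x, ...) {
  plot(x$tree, labels = FALSE, main = "Ward clustering of |correlation| distance",
       xlab = "", sub = "", ...)
}
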