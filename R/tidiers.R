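# broom-style tidy()/glance() methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the merged predictions of an evaluation
#'
#' @param x A `gait_eval`.
#' @param ... Unused.
#' @return The pooled per-trial predictions tibble.
#' @export
tidy.gait_eval <- function(x, ...) x$predictions

#' One-row evaluation summary
#'
#' @param x A `gait_eval`.
#' @param ... Unused.
#' @return Tibble: merged AUROC with CI and threshold-0.5 metrics.
#' @export
glance.gait_eval <- function(x, ...) {
  bind_cols(tibble(auroc = x$auroc, ci_lo = x$ci[1], ci_hi = x$ci[2]),
            x$metrics,
            tibble(n_predictions = nrow(x$predictions),
                   n_repeats = x$n_repeats))
}

#' Tidy a model grid
#'
#' @param x A `gait_grid`.
#' @param ... Unused.
#' @return The grid tibble without the list-column of eval objects.
#' @export
tidy.gait_grid <- function(x, ...) as_tibble(x) |> select(-any_of("eval"))

#' Tidy a cluster-importance report
#'
#' @param x A `cluster_importance`.
#' @param ... Unused.
#' @return Tibble ranked by mean AUROC drop.
#' @export
tidy.cluster_importance <- function(x, ...) as_tibble(x) |> arrange(.data$rank)

#' Tidy a feature clustering
#'
#' @param x A `feature_clusters`.
#' @param ... Unused.
#' @return The feature-to-cluster assignment tibble.
#' @export
tidy.feature_clusters <- function(x, ...) x$assignment

#' Tidy a Welch test result
#'
#' @param x A `welch_result`.
#' @param ... Unused.
#' @return The one-row result tibble.
#' @export
tidy.welch_result <- function(x, ...) as_tibble(x)

#' Tidy a stride table
#'
#' @param x A `stride_table`.
#' @param ... Unused.
#' @return Per-stride tibble (length, time).
#' @export
tidy.stride_table <- function(x, ...) x$strides

#' One-row stride summary
#'
#' @param x A `stride_table`.
#' @param ... Unused.
#' @return The spatiotemporal summary features.
#' @export
glance.stride_table <- function(x, ...) x$summary
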