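# feature-correlation clustering, cluster permutation importance, Welch t-tests

#' Cluster features by absolute Pearson correlation
#'
#' Distance `1 - |rho|` between features, Ward linkage, tree cut at
#' `n_clusters`. Captures the multi-collinearity structure of the kinematic
#' feature set so importance can be assessed per correlated group rather
#' than per feature. Constant features get correlation 0 (distance 1) with
#' a warning.
#'
#' @param x Feature matrix / tibble (rows = trials, >= 3).
#' @param n_clusters Number of clusters to cut (default 3).
#' @return A `feature_clusters`: `assignment` tibble (feature, cluster),
#'   the `hclust` tree, and `n_clusters`.
#' @export
correlation_clusters <- function(x, n_clusters = 3) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L) {
    abort("Need >= 2 features and >= 3 rows to cluster.",
          class = "vestigait_error_empty_input")
  }
  sds <- apply(x, 2, sd)
  if (any(sds < 1e-12)) {
    warn(sprintf("%d constant feature(s); correlations set to 0.",
                 sum(sds < 1e-12)))
  }
  C <- suppressWarnings(cor(x))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  tree <- hclust(as.dist(1 - abs(C)), method = "ward.D2")
  cl <- cutree(tree, k = n_clusters)
  structure(list(
    assignment = tibble(feature = colnames(x), cluster = unname(cl)),
    tree = tree, n_clusters = n_clusters
  ), class = "feature_clusters")
}

#' Rank feature clusters by permutation AUROC drop
#'
#' For each cluster and permutation repeat, the rows of all features in the
#' cluster are shuffled with one shared row permutation (preserving the
#' intra-cluster correlation the clustering was built to respect) and the
#' model's test AUROC is recomputed. The drop is baseline minus permuted
#' AUROC, summarized by its mean and a percentile CI; clusters are ranked by
#' mean drop (negative drops are reported as-is).
#'
#' @param model Fitted probability forest (from [tune_and_train()]'s
#'   `$model`, or any object [predict()]-compatible via `predict_prob`).
#' @param x Test feature matrix on the scale the model was trained on.
#' @param labels Test labels (both classes required).
#' @param clusters A `feature_clusters` over the columns of `x`.
#' @param n_perm Permutation repeats per cluster.
#' @param seed Seed for the shared permutations.
#' @return A `cluster_importance` tibble: cluster, n_features, mean_drop,
#'   ci_lo, ci_hi, rank; baseline AUROC kept as an attribute.
#' @export
cluster_permutation_importance <- function(model, x, labels, clusters,
                                           n_perm = 100, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("Test set needs both classes.",
          class = "vestigait_error_undefined_auroc")
  }
  baseline <- auroc(labels, predict_prob(model, x))
  set.seed(seed)
  ids <- sort(unique(clusters$assignment$cluster))
  rows <- map(ids, function(cl) {
    cols <- clusters$assignment$feature[clusters$assignment$cluster == cl]
    drops <- map_dbl(seq_len(n_perm), function(r) {
      idx <- sample.int(nrow(x))
      xp <- x
      xp[, cols] <- x[idx, cols, drop = FALSE]
      baseline - auroc(labels, predict_prob(model, xp))
    })
    tibble(cluster = cl, n_features = length(cols),
           mean_drop = mean(drops),
           ci_lo = unname(quantile(drops, 0.025)),
           ci_hi = unname(quantile(drops, 0.975)))
  }) |> list_rbind()
  rows <- rows |> mutate(rank = rank(-.data$mean_drop, ties.method = "first"))
  attr(rows, "baseline_auroc") <- baseline
  class(rows) <- c("cluster_importance", class(rows))
  rows
}

welch_from_stats <- function(m_a, sd_a, n_a, m_b, sd_b, n_b) {
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    if (m_a == m_b) {
      return(tibble(m_a = m_a, sd_a = sd_a, n_a = n_a,
                    m_b = m_b, sd_b = sd_b, n_b = n_b,
                    t = 0, df = n_a + n_b - 2, p = 1, r = 0))
    }
    abort("Zero variance in both groups with distinct means: t is infinite.",
          class = "vestigait_error_infinite_t")
  }
  t_stat <- (m_a - m_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * pt(-abs(t_stat), df)
  tibble(m_a = m_a, sd_a = sd_a, n_a = n_a,
         m_b = m_b, sd_b = sd_b, n_b = n_b,
         t = t_stat, df = df, p = p,
         r = sqrt(t_stat^2 / (t_stat^2 + df)))
}

#' Welch two-sample t-test with effect size r
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and
#' effect size `r = sqrt(t^2 / (t^2 + df))`. Group A is reported first;
#' calling with controls as A and the vestibular group as B fixes the sign
#' convention (positive t = controls larger).
#'
#' @param a,b Numeric samples (>= 2 each).
#' @return A one-row `welch_result` tibble: group summaries (M, SD, n),
#'   `t`, `df`, two-sided `p`, and `r`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Welch t-test needs >= 2 samples per group.",
          class = "vestigait_error_empty_input")
  }
  out <- welch_from_stats(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  class(out) <- c("welch_result", class(out))
  out
}

#' Welch t-test from printed group summaries
#'
#' Identical formulas to [welch_t()], computed from group means, SDs and
#' sizes -- the reproduction path when only summary statistics are
#' available.
#'
#' @param m_a,sd_a,n_a Group A summary (mean, SD, n).
#' @param m_b,sd_b,n_b Group B summary.
#' @return A one-row `welch_result` tibble.
#' @export
welch_t_from_summary <- function(m_a, sd_a, n_a, m_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L || sd_a < 0 || sd_b < 0) {
    abort("Summaries need n >= 2 and SD >= 0.",
          class = "vestigait_error_empty_input")
  }
  out <- welch_from_stats(m_a, sd_a, n_a, m_b, sd_b, n_b)
  class(out) <- c("welch_result", class(out))
  out
}

#' Welch t-tests for a set of dataset features
#'
#' One test per feature, controls (label 0) minus vestibular (label 1), so
#' positive t means the control group is larger.
#'
#' @param dataset A task dataset tibble with a `label` column.
#' @param features Feature column names to test.
#' @return Tibble with one `welch_result` row per feature.
#' @export
welch_table <- function(dataset, features) {
  map(features, function(f) {
    bind_cols(tibble(feature = f),
              welch_t(dataset[[f]][dataset$label == 0],
                      dataset[[f]][dataset$label == 1]))
  }) |> list_rbind()
}
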