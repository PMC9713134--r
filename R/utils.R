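# shared numeric helpers

#' Area under the ROC curve by midranks
#'
#' Threshold-free binary classification performance, computed with the
#' rank-sum (Mann-Whitney) identity. Tied scores get midranks, so a
#' constant score gives exactly 0.5.
#'
#' @param labels Binary vector (0 = control, 1 = vestibular).
#' @param scores Numeric scores; larger means more likely class 1.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUROC undefined: only one class present.",
          class = "vestigait_error_undefined_auroc")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC sweep for plotting: one point per distinct threshold
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- as.integer(labels)[ord]
  tp <- cumsum(labels == 1L)
  fp <- cumsum(labels == 0L)
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  tibble(
    fpr = c(0, fp[keep] / max(1L, sum(labels == 0L))),
    tpr = c(0, tp[keep] / max(1L, sum(labels == 1L)))
  )
}

# rotation matrix from a rotation vector (axis * angle), Rodrigues form
rotvec_to_matrix <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

unit_vector <- function(v) v / sqrt(sum(v^2))

# angle between two directions in degrees (sign-insensitive when axis = TRUE)
angle_deg <- function(u, v, axis = FALSE) {
  d <- sum(unit_vector(u) * unit_vector(v))
  if (axis) d <- abs(d)
  acos(max(-1, min(1, d))) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

row_norms <- function(m) sqrt(rowSums(m^2))

# trapezoidal cumulative integral of each column, dt = 1/fs, starts at 0
cumtrapz_fs <- function(m, fs) {
  m <- as.matrix(m)
  pracma::cumtrapz(seq_len(nrow(m)), m) / fs
}
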