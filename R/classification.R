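#' ROC curve and AUC for a continuous score against binary labels
#'
#' AUC is computed from the rank statistic `U/(n1*n0)` with ties counted
#' one half. The curve sweeps thresholds from high to low over the distinct
#' observed scores (plus `Inf`), predicting positive where
#' `score > threshold`, so TPR and FPR are non-decreasing along the sweep.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1, logical, or two-level factor; the
#'   higher level is the positive class).
#' @return Object of class `"roc_result"`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `youden_cutoff`, `accuracy_at_cutoff`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # midranks: ties count 1/2 in U
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y == 1] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] > t), numeric(1))
  out <- structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
                   class = "roc_result")
  out$youden_cutoff <- youden_cutoff(out)
  out$accuracy_at_cutoff <- accuracy_at_cutoff(scores, y, out$youden_cutoff)
  out$scores <- scores
  out$labels <- y
  out
}

#' Youden-J optimal cutoff from a ROC sweep
#'
#' Maximizes `J = TPR - FPR` over candidate cutoffs (the observed score
#' values plus `-Inf`), predicting positive where `score > cutoff`. Among
#' tied maximizers the smallest cutoff is returned.
#'
#' @param roc A `"roc_result"` from [roc_auc()].
#' @return The selected cutoff value.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  fin <- is.finite(roc$thresholds)
  cand <- c(-Inf, roc$thresholds[fin])
  tpr <- c(1, roc$tpr[fin])
  fpr <- c(1, roc$fpr[fin])
  j <- tpr - fpr
  best <- which(j == max(j))
  min(cand[best])
}

#' Classification accuracy at a fixed cutoff
#'
#' Predicts positive where `score > cutoff` and returns the fraction of
#' correct assignments.
#'
#' @inheritParams roc_auc
#' @param cutoff Threshold.
#' @return Fraction in \[0, 1\].
#' @export
accuracy_at_cutoff <- function(scores, labels, cutoff) {
  y <- as_binary_labels(labels)
  mean((scores > cutoff) == (y == 1))
}

#' Wilcoxon rank-sum test without continuity correction
#'
#' Exact permutation p-value when both groups have at most 50 observations
#' and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and no continuity correction. Two-sided.
#'
#' @param x,y Numeric vectors.
#' @return List: `statistic` (the rank-sum U for `x`), `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 50 && length(y) <= 50
  wt <- stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Squared Pearson correlation with its t-test p-value
#'
#' @param x,y Numeric vectors of length >= 3 with nonzero variance.
#' @return List: `r2`, `p` (from `t = r*sqrt((n-2)/(1-r^2))`).
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p = ct$p.value)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; Youden cutoff = %s (accuracy %.3f)\n",
              x$auc, format(x$youden_cutoff, digits = 4),
              x$accuracy_at_cutoff))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "False positive rate",
                 ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1),
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    return(as.integer(labels == levels(labels)[2]))
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels == 1)
}
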