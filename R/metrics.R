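#' Threshold-free and thresholded detection metrics
#'
#' Computes AUROC (by the Mann-Whitney rank statistic, equivalent to
#' trapezoidal ROC integration, with ties given half credit), AUPRC (step
#' integration of the precision-recall curve over descending unique score
#' thresholds), and precision / recall / F1 of the positive (seizure)
#' class at a fixed decision threshold.
#'
#' With only one class present AUROC and AUPRC are undefined and reported
#' as `NA` (with a message); the thresholded metrics are still computed.
#'
#' @param scores Numeric vector of detector scores (seizure-class
#'   probability or any monotone score).
#' @param labels Binary vector (0/1, logical, or factor with two levels)
#'   with 1 = seizure.
#' @param threshold Decision threshold for precision/recall/F1; a score
#'   `>= threshold` predicts seizure.
#' @param maximize_f1 If `TRUE`, ignore `threshold` and pick the score
#'   threshold maximizing F1 (reported in the output).
#' @return A one-row tibble of class `eval_report`: `auroc`, `auprc`,
#'   `precision`, `recall`, `f1`, `decision_threshold`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' compute_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
compute_metrics <- function(scores, labels, threshold = 0.5,
                            maximize_f1 = FALSE) {
  labels <- as_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)

  auroc <- auprc <- NA_real_
  if (n_pos > 0L && n_neg > 0L) {
    r <- rank(scores, ties.method = "average")
    auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
    auprc <- auprc_step(scores, labels)
  } else {
    message("only one class present: AUROC/AUPRC undefined (NA)")
  }

  if (maximize_f1 && n_pos > 0L) {
    cand <- sort(unique(scores))
    f1s <- vapply(cand, function(th) threshold_metrics(scores, labels, th)$f1,
                  numeric(1))
    threshold <- cand[which.max(f1s)]
  }
  tm <- threshold_metrics(scores, labels, threshold)

  out <- tibble::tibble(
    auroc = auroc, auprc = auprc,
    precision = tm$precision, recall = tm$recall, f1 = tm$f1,
    decision_threshold = threshold, n_pos = n_pos, n_neg = n_neg
  )
  class(out) <- c("eval_report", class(out))
  out
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels)) labels <- as.integer(labels == "seizure")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1, logical, or \"seizure\"/\"background\")",
         call. = FALSE)
  }
  labels
}

threshold_metrics <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

# Step-integrated area under the precision-recall curve: thresholds sweep
# the unique scores in descending order; each recall increment contributes
# the precision at that threshold.
auprc_step <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each tie group
  tp <- tp[keep]; fp <- fp[keep]
  n_pos <- sum(y)
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUROC %.4f | AUPRC %.4f | P %.4f R %.4f F1 %.4f @ %.3g (n+ %d, n- %d)\n",
    x$auroc, x$auprc, x$precision, x$recall, x$f1, x$decision_threshold,
    x$n_pos, x$n_neg))
  invisible(x)
}
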