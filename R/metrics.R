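# Binary-classification metrics implemented from the confusion-matrix
# definitions, with rank-based AUROC and average-precision AUPRC.

#' Confusion-matrix counts at a threshold
#'
#' A score is called positive when `score >= threshold` (boundary inclusive).
#'
#' @param labels 0/1 vector of true labels.
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  if (!length(labels)) stop("empty input")
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  list(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L)
  )
}

#' Compute the full metric panel
#'
#' Accuracy, precision, recall, specificity, F1, Matthews correlation
#' coefficient, AUROC and AUPRC.  Zero-denominator conventions: precision is 0
#' when no positive predictions exist; MCC is 0 when any of its four
#' denominator factors is 0; F1 is 0 when precision + recall is 0.  With
#' single-class labels the threshold metrics are still reported but AUROC and
#' AUPRC are undefined: they are set to `NA` and `curve_error` records why.
#'
#' @inheritParams confusion_counts
#' @return Object of class `metrics_report`: the eight metrics, the
#'   `threshold`, the confusion `counts`, and `curve_error` (`NULL` when the
#'   curves are defined).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  cc <- confusion_counts(labels, scores, threshold)
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n <- TP + TN + FP + FN
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  specificity <- if (TN + FP == 0) 0 else TN / (TN + FP)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  den <- c(TP + FP, TP + FN, TN + FP, TN + FN)
  mcc <- if (any(den == 0)) 0 else
    (TP * TN - FP * FN) / sqrt(prod(as.numeric(den)))
  single_class <- length(unique(as.integer(labels))) < 2L
  structure(
    list(
      accuracy = (TP + TN) / n,
      precision = precision,
      recall = recall,
      specificity = specificity,
      f1 = f1,
      mcc = mcc,
      auroc = if (single_class) NA_real_ else auroc(labels, scores),
      auprc = if (single_class) NA_real_ else auprc(labels, scores),
      threshold = threshold,
      counts = cc,
      curve_error = if (single_class) "single-class labels: ROC/PR undefined" else NULL
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Binary classification metrics (threshold =", x$threshold, ")\n")
  m <- unlist(x[c("accuracy", "precision", "recall", "specificity",
                  "f1", "mcc", "auroc", "auprc")])
  print(round(m, digits))
  if (!is.null(x$curve_error)) cat("note:", x$curve_error, "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with midrank handling of tied
#' scores — the probability that a random positive outscores a random
#' negative, ties counting one half.
#'
#' @inheritParams confusion_counts
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("AUROC undefined: labels contain one class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Average precision with step interpolation: scores are swept from high to
#' low over unique thresholds (tied scores grouped), and each increment in
#' recall is weighted by the precision at that threshold.
#'
#' @inheritParams confusion_counts
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  pts <- pr_points(labels, scores)
  rec <- c(0, pts$recall)
  sum(diff(rec) * pts$precision)
}

#' ROC curve points
#'
#' One point per unique threshold (descending), preceded by (0, 0); tied
#' scores enter together.
#'
#' @inheritParams confusion_counts
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  sw <- .threshold_sweep(labels, scores)
  data.frame(
    threshold = c(Inf, sw$threshold),
    fpr = c(0, sw$fp / sw$nn),
    tpr = c(0, sw$tp / sw$np)
  )
}

#' Precision-recall curve points
#'
#' One point per unique threshold (descending); tied scores enter together.
#'
#' @inheritParams confusion_counts
#' @return Data frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(labels, scores) {
  sw <- .threshold_sweep(labels, scores)
  data.frame(
    threshold = sw$threshold,
    recall = sw$tp / sw$np,
    precision = sw$tp / (sw$tp + sw$fp)
  )
}

# Cumulative TP/FP over unique descending thresholds (ties grouped).
.threshold_sweep <- function(labels, scores) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("curve undefined: labels contain one class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- which(!duplicated(s, fromLast = TRUE))
  list(
    threshold = s[last],
    tp = cumsum(y)[last],
    fp = cumsum(1L - y)[last],
    np = np, nn = nn
  )
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y * log(p) + (1 - y) * log(1 - p))`; predicted probabilities are
#' clipped to `[clip, 1 - clip]` for numerical safety.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities, same length.
#' @param clip Clipping bound (default 1e-7).
#' @return The mean loss (a scalar).
#' @export
bce_loss <- function(labels, probs, clip = 1e-7) {
  p <- pmin(pmax(probs, clip), 1 - clip)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
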