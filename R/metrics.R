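#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities, `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))`.  Probabilities
#' are clipped to `[eps, 1 - eps]` so degenerate predictions do not produce
#' infinite loss.
#'
#' @param labels binary vector (0/1).
#' @param prob numeric vector of predicted probabilities, same length.
#' @param eps clipping constant, default `1e-7`.
#' @return Non-negative scalar loss.
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bce_loss <- function(labels, prob, eps = 1e-7) {
  if (length(labels) != length(prob))
    stop("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# tie-aware rank AUC: probability that a random positive outranks a random
# negative, ties counting one half
.auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for m6A site prediction
#'
#' Thresholds probabilities into class calls, builds the confusion counts
#' and computes the six standard evaluation metrics: accuracy, sensitivity
#' (recall on positives), specificity (recall on negatives), Matthews
#' correlation coefficient, F1 score and AUC.  AUC is the tie-aware rank
#' statistic (probability that a random positive scores above a random
#' negative, ties counting one half), which needs no ROC interpolation and
#' is well defined with tied scores.
#'
#' With a single-class input the undefined metrics (and AUC) are returned as
#' `NaN` with a warning; accuracy is always defined.
#'
#' @param labels binary vector (0/1).
#' @param prob predicted probabilities in `[0, 1]`.
#' @param threshold classification threshold, default 0.5 (a probability
#'   `>= threshold` is called positive).
#' @return Object of class `"metrics_report"`: list with `counts`
#'   (`tp`, `tn`, `fp`, `fn`), the six metrics, `threshold` and `n`.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
#' @export
compute_metrics <- function(labels, prob, threshold = 0.5) {
  if (length(labels) != length(prob))
    stop("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)

  acc  <- (tp + tn) / length(labels)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NaN
  f1  <- if (2 * tp + fp + fn > 0) tp / (tp + (fp + fn) / 2) else NaN
  auc <- .auc_rank(labels, prob)
  if (anyNA(c(sens, spec, mcc, f1, auc)))
    warning("some metrics are undefined for this input ",
            "(single-class labels or empty confusion margins)")

  structure(list(counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 mcc = mcc, f1 = f1, auc = auc,
                 threshold = threshold, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Classification metrics (n = ", x$n,
      ", threshold = ", x$threshold, ")\n", sep = "")
  cat("  confusion: TP ", x$counts["tp"], "  TN ", x$counts["tn"],
      "  FP ", x$counts["fp"], "  FN ", x$counts["fn"], "\n", sep = "")
  m <- unlist(x[c("accuracy", "sensitivity", "specificity",
                  "mcc", "f1", "auc")])
  print(round(m, digits))
  invisible(x)
}

#' @method as.data.frame metrics_report
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, mcc = x$mcc, f1 = x$f1,
             auc = x$auc)
}
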