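#' Confusion matrix counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives; their sum must be > 0.
#' @return Object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Standard two-class metrics:
#' accuracy \eqn{= (TP+TN)/(TP+FP+FN+TN)},
#' precision \eqn{= TP/(TP+FP)},
#' recall (sensitivity) \eqn{= TP/(TP+FN)},
#' specificity \eqn{= TN/(TN+FP)},
#' F1 \eqn{= 2 \cdot precision \cdot recall / (precision + recall)}.
#' A metric whose denominator is zero is reported as `NA` (undefined — not 0)
#' with a warning naming it.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list: `accuracy`, `precision`, `recall`, `specificity`, `f1`,
#'   plus `support` (named counts of true positives+false negatives and true
#'   negatives+false positives, i.e. per-class sample counts).
#' @examples
#' metrics_from_confusion(confusion_matrix(tp = 40, tn = 30, fp = 20, fn = 10))
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator)", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  with(cm, {
    accuracy <- (tp + tn) / (tp + fp + fn + tn)
    precision <- rate(tp, tp + fp, "precision")
    recall <- rate(tp, tp + fn, "recall")
    specificity <- rate(tn, tn + fp, "specificity")
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
      warning("f1 is undefined (zero denominator)", call. = FALSE)
      NA_real_
    } else 2 * precision * recall / (precision + recall)
    list(accuracy = accuracy, precision = precision, recall = recall,
         specificity = specificity, f1 = f1,
         support = c(positive = tp + fn, negative = tn + fp))
  })
}

# ROC-AUC over held-out scores (trapezoidal, via pROC) and negative log loss
# (natural log, probabilities clipped at 1e-15). `scores`/`prob1` are the
# scores/probabilities for the positive class; `truth` is 0/1.
score_auc <- function(truth, scores) {
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

neg_log_loss <- function(truth, prob1, clip = 1e-15) {
  p <- pmin(pmax(prob1, clip), 1 - clip)
  mean(ifelse(truth == 1, log(p), log(1 - p)))
}
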