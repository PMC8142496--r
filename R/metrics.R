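#' Confusion-matrix counts for binary predictions
#'
#' @param truth,pred Equal-length vectors of 0/1 labels.
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred must have equal length")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("truth and pred must be binary 0/1")
  }
  c(tp = sum(truth == 1 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0))
}

#' Confusion-matrix statistics
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, F-score
#' `2*TP/(2*TP+FP+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`.
#' Zero-denominator conventions: sensitivity/specificity/precision/F are 0
#' (with a warning for precision when nothing was predicted positive); MCC
#' is 0 whenever any factor under the root vanishes.
#'
#' @param counts Named vector from [confusion_counts()] (names `tp`, `tn`,
#'   `fp`, `fn`).
#' @return Named numeric vector `acc`, `sn`, `sp`, `pre`, `f`, `mcc`, all on
#'   the [0, 1] scale (MCC in [-1, 1]).
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); tn <- as.numeric(counts[["tn"]])
  fp <- as.numeric(counts[["fp"]]); fn <- as.numeric(counts[["fn"]])
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  if (tp + fp == 0) warning("no positive predictions: precision defined as 0")
  denom_sq <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  c(acc = (tp + tn) / total,
    sn  = safe_div(tp, tp + fn),
    sp  = safe_div(tn, tn + fp),
    pre = safe_div(tp, tp + fp),
    f   = safe_div(2 * tp, 2 * tp + fp + fn),
    mcc = if (denom_sq == 0) 0 else (tp * tn - fp * fn) / sqrt(denom_sq))
}

#' ROC curve from scores
#'
#' Sensitivity versus 1 - specificity over thresholds at the distinct score
#' values (descending, ties grouped), with the endpoints (0,0) and (1,1)
#' always present.  Both coordinates are non-decreasing along the curve.
#'
#' @param truth 0/1 labels with at least one instance of each class.
#' @param scores Numeric scores; larger means more positive.
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`.  The first row
#'   (0,0) carries threshold `Inf`, the last (1,1) the minimum score.
#' @export
roc_curve <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("truth and scores must align")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires at least one instance of each class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # Cumulative counts at the boundaries between distinct score values.
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y == 1)[last_of_tie]
  cum_fp <- cumsum(y == 0)[last_of_tie]
  data.frame(threshold = c(Inf, s[last_of_tie]),
             fpr = c(0, cum_fp / n_neg),
             tpr = c(0, cum_tp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; on tie-grouped curves this equals
#' the rank statistic `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param truth 0/1 labels.
#' @param scores Numeric scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(truth, scores) {
  curve <- roc_curve(truth, scores)
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Full evaluation report for scored predictions
#'
#' Hard labels are `score > threshold` (a score exactly at the threshold is
#' called negative); confusion counts, the derived statistics and ROC/AUC
#' are assembled into one report.
#'
#' @param truth 0/1 labels.
#' @param scores Positive-class scores in [0, 1].
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `"phos_metrics"`: `counts`, `metrics`, `auc`,
#'   `roc`, `threshold`, `n`.
#' @export
evaluate_predictions <- function(truth, scores, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  counts <- confusion_counts(truth, pred)
  both <- sum(truth == 1) > 0 && sum(truth == 0) > 0
  structure(list(counts = counts,
                 metrics = compute_metrics(counts),
                 auc = if (both) roc_auc(truth, scores) else NA_real_,
                 roc = if (both) roc_curve(truth, scores) else NULL,
                 threshold = threshold,
                 n = length(truth)),
            class = "phos_metrics")
}

#' @export
print.phos_metrics <- function(x, digits = 3, ...) {
  m <- x$metrics
  cat(sprintf("n = %d   TP %d  TN %d  FP %d  FN %d\n", x$n,
              x$counts[["tp"]], x$counts[["tn"]],
              x$counts[["fp"]], x$counts[["fn"]]))
  cat(sprintf("ACC %.1f%%  SN %.1f%%  SP %.1f%%  PRE %.1f%%  F %.1f%%  MCC %s  AUC %s\n",
              100 * m[["acc"]], 100 * m[["sn"]], 100 * m[["sp"]],
              100 * m[["pre"]], 100 * m[["f"]],
              format(round(m[["mcc"]], digits)),
              if (is.na(x$auc)) "NA" else format(round(x$auc, digits))))
  invisible(x)
}
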