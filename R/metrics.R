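# Confusion-matrix metrics and rank-based AUC. Undefined ratios (zero
# denominators) are NaN rather than 0 so that averaging over cross-validation
# iterations skips them instead of biasing the mean.

#' Metrics from confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; at least one must be
#'   positive.
#' @return named numeric vector with `acc`, `sensitivity`, `specificity`,
#'   `recall` (= sensitivity), `precision`, `f_measure`; NaN where the
#'   denominator is zero.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  prec <- ratio(tp, tp + fp)
  fm <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) NaN else
    2 * prec * sens / (prec + sens)
  c(acc = acc, sensitivity = sens, specificity = spec,
    recall = sens, precision = prec, f_measure = fm)
}

#' Confusion counts from predicted and true labels
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive the positive class label.
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  c(tp = sum(predicted == positive & truth == positive),
    fp = sum(predicted == positive & truth != positive),
    tn = sum(predicted != positive & truth != positive),
    fn = sum(predicted != positive & truth == positive))
}

#' Rank-based AUC (Mann-Whitney estimate)
#'
#' The probability that a randomly chosen positive instance is scored higher
#' than a randomly chosen negative one; tied pairs count 0.5.
#'
#' @param scores_pos scores of the positive instances.
#' @param scores_neg scores of the negative instances.
#' @return the AUC, or NaN (with a warning) when either vector is empty.
#' @export
rank_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: one class has no instances")
    return(NaN)
  }
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
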