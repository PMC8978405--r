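#' Precision and recall at a threshold
#'
#' Confusion-matrix ratios at a probability threshold. Precision is defined
#' as 0 (with a message) when nothing is predicted positive.
#'
#' @param y_true Binary 0/1 labels.
#' @param y_score Predicted scores/probabilities, same length.
#' @param threshold Scores `>= threshold` are predicted positive.
#' @return Named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(y_true, y_score, threshold = 0.5) {
  if (length(y_true) != length(y_score)) {
    stop("y_true and y_score lengths differ: ", length(y_true), " vs ",
         length(y_score))
  }
  y_true <- as.integer(y_true)
  stopifnot(all(y_true %in% c(0L, 1L)))
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  precision <- if (tp + fp == 0) {
    message("precision_recall: no positive predictions; precision set to 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = precision, recall = recall)
}

#' f-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; 0 when both inputs are 0.
#' `beta = 1` weights precision and recall equally; `beta = 2` weights recall
#' higher, appropriate when negatives are unvalidated samples from unknown
#' pairs and precision is unreliable.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @param beta Positive weight on recall.
#' @return The f-beta score in `[0, 1]`.
#' @export
#' @examples
#' f_beta(0.8813, 0.9263, beta = 2)
f_beta <- function(precision, recall, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Threshold-free ranking metrics: AUC and AUPR
#'
#' AUC is the Mann-Whitney probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with ties counting one half
#' (computed from rank sums). AUPR is the area under the precision-recall
#' curve by the step-wise average-precision construction: the mean, over
#' positives in score-descending order, of the precision at each positive's
#' rank.
#'
#' @inheritParams precision_recall
#' @return Named numeric vector `c(auc =, aupr =)`.
#' @export
ranking_metrics <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) stop("length mismatch")
  y_true <- as.integer(y_true)
  stopifnot(all(y_true %in% c(0L, 1L)))
  n_pos <- sum(y_true == 1L)
  n_neg <- sum(y_true == 0L)
  if (n_pos == 0 || n_neg == 0) stop("both classes are required for ranking metrics")
  r <- rank(y_score, ties.method = "average")
  auc <- (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # average precision over the distinct score thresholds:
  # AP = sum_k (R_k - R_{k-1}) * P_k, descending thresholds, R_0 = 0
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_score[ord]
  yt <- y_true[ord]
  cum_tp <- cumsum(yt)
  at_threshold <- !duplicated(ys, fromLast = TRUE)  # last index of each tied block
  tp <- cum_tp[at_threshold]
  k <- which(at_threshold)
  prec <- tp / k
  rec <- tp / n_pos
  aupr <- sum((rec - c(0, utils::head(rec, -1))) * prec)
  c(auc = auc, aupr = aupr)
}

all_metrics <- function(y_true, y_score, beta = 1, threshold = 0.5) {
  pr <- suppressMessages(precision_recall(y_true, y_score, threshold))
  rk <- ranking_metrics(y_true, y_score)
  c(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
    fbeta = f_beta(pr[["precision"]], pr[["recall"]], beta),
    aupr = unname(rk["aupr"]), auc = unname(rk["auc"]))
}
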