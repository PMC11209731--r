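#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with average ranks, so tied scores count 1/2.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 vector, same length; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) abort("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average of the precision values at each positive hit when scores are
#' ranked in descending order (stable order on ties).
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  if (np == 0L || all(labels == 1L)) abort("AUPR needs both classes present")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1L]) / np
}

#' Evaluate scored positives and negatives
#'
#' Confusion counts at a threshold (TPR = TP/(TP+FN), FPR = FP/(FP+TN),
#' ACC = (TP+TN)/total) plus threshold-free AUROC and AUPR.
#'
#' @param pos_scores Scores of the true (positive) edges.
#' @param neg_scores Scores of the negative pairs.
#' @param threshold Decision threshold for the counts (default 0.5).
#' @return One-row tibble: TP, FP, TN, FN, TPR, FPR, ACC, AUROC, AUPR.
#' @export
evaluate_scores <- function(pos_scores, neg_scores, threshold = 0.5) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    abort("evaluation needs nonempty positive and negative score sets")
  }
  tp <- sum(pos_scores >= threshold)
  fn <- length(pos_scores) - tp
  fp <- sum(neg_scores >= threshold)
  tn <- length(neg_scores) - fp
  scores <- c(pos_scores, neg_scores)
  labels <- rep(c(1L, 0L), c(length(pos_scores), length(neg_scores)))
  tibble::tibble(
    TP = tp, FP = fp, TN = tn, FN = fn,
    TPR = tp / (tp + fn), FPR = fp / (fp + tn),
    ACC = (tp + tn) / (tp + fp + tn + fn),
    AUROC = auroc(scores, labels),
    AUPR = aupr(scores, labels))
}
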