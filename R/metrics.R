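# Ranking metrics shared by the evaluation harness. Implemented here
# because the disease-centric rank-transform-then-pool protocol is the
# point; cross-checked in the test suite against a brute-force
# concordant-pair oracle and pROC.

#' Area under the ROC curve from scores and binary labels
#'
#' Mann-Whitney form: the probability that a random positive outscores
#' a random negative, with ties counted half. Equivalent to the
#' rank-sum statistic, so tied scores receive average ranks.
#'
#' @param scores numeric vector of prediction scores (finite).
#' @param labels 0/1 vector of the same length, at least one of each.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  nP <- sum(labels == 1L)
  nN <- sum(labels == 0L)
  if (nP == 0L || nN == 0L) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  if (any(!is.finite(scores))) stop("non-finite scores")
  r <- rank(scores)
  (sum(r[labels == 1L]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise precision-recall integration in the average-precision
#' convention: examples are sorted by descending score and AP is the
#' mean over positives of the precision at each positive's position.
#' Ties are broken by stable (original) order, which is deterministic.
#'
#' @inheritParams aucScore
#' @return AUPR in (0, 1].
#' @export
auprScore <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  nP <- sum(labels == 1L)
  if (nP == 0L) stop("AUPR undefined: no positives")
  if (any(!is.finite(scores))) stop("non-finite scores")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1L]) / nP
}
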