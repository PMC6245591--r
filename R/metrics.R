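#' ROC/PR evaluation of binary interaction scores
#'
#' AUC is computed by the rank-sum (Wilcoxon) statistic, with tied scores
#' contributing half credit. AUPR integrates the precision-recall step
#' curve: thresholds sweep the distinct score values from high to low, tied
#' scores enter together, and each threshold contributes its precision
#' times the recall increment (no interpolation).
#'
#' @param labels Vector of 0/1 labels (1 = interacting pair).
#' @param scores Numeric prediction scores, higher = more confident.
#' @return An object of class `ddi_eval`: list with `auc`, `aupr`,
#'   `roc` (tibble: threshold, fpr, tpr), `pr` (tibble: threshold, recall,
#'   precision), `n_pos`, `n_neg`, `protocol`.
#' @examples
#' score_binary(c(1, 1, 0, 0), c(4, 2, 3, 1))$auc  # 0.75
#' @export
score_binary <- function(labels, scores) {
  labels <- as.numeric(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) abort("labels and scores must have equal length")
  if (anyNA(labels) || anyNA(scores)) abort("labels and scores must not contain NA")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos < 1 || n_neg < 1) {
    abort("undefined metric: need at least one positive and one negative sample")
  }

  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_last <- which(diff(s) != 0)
  cuts <- c(grp_last, length(s))              # last index of each tie group
  tp <- cumsum(y)[cuts]
  n_at <- cuts
  fp <- n_at - tp
  recall <- tp / n_pos
  precision <- tp / n_at
  tpr <- recall
  fpr <- fp / n_neg
  aupr <- sum(diff(c(0, recall)) * precision)

  structure(
    list(
      auc = auc,
      aupr = aupr,
      roc = tibble::tibble(threshold = c(Inf, s[cuts]),
                           fpr = c(0, fpr), tpr = c(0, tpr)),
      pr = tibble::tibble(threshold = s[cuts], recall = recall, precision = precision),
      n_pos = n_pos,
      n_neg = n_neg,
      protocol = "conventional"
    ),
    class = "ddi_eval"
  )
}

#' ROC/PR evaluation of signed (comprehensive) interaction scores
#'
#' Comprehensive prediction must rank both enhancive and degressive
#' interactions above non-interactions while the score sign carries the
#' type. The protocol relabels degressive pairs as positives and negates
#' their scores (a confidently negative score is a confident degressive
#' call), keeps enhancive pairs as positives with their original scores,
#' treats non-interactions as negatives, and then applies [score_binary()].
#'
#' @param labels Vector over \{-1, 0, +1\}: enhancive, none, degressive.
#' @param scores Numeric signed prediction scores.
#' @return A `ddi_eval` object (see [score_binary()]) with
#'   `protocol = "comprehensive"`.
#' @examples
#' score_comprehensive(c(1, -1, 0), c(2.0, -1.5, 0.1))$auc  # 1
#' @export
score_comprehensive <- function(labels, scores) {
  labels <- as.numeric(labels)
  scores <- as.numeric(scores)
  if (length(labels) != length(scores)) abort("labels and scores must have equal length")
  if (!all(labels %in% c(-1, 0, 1))) abort("labels must be -1, 0 or +1")
  if (sum(labels != 0) < 1 || sum(labels == 0) < 1) {
    abort("undefined metric: need at least one interaction and one non-interaction")
  }
  flipped <- ifelse(labels == -1, -scores, scores)
  out <- score_binary(as.integer(labels != 0), flipped)
  out$protocol <- "comprehensive"
  out
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat(sprintf("%s evaluation: AUC = %.4f, AUPR = %.4f (%d positives, %d negatives)\n",
              x$protocol, x$auc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}
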