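#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) estimator: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted half.
#' Computed from midranks, so it is exact and O(n log n).
#'
#' @param scores Numeric prediction scores (any monotone scale).
#' @param labels Binary labels (0/1 or logical), same length as `scores`.
#' @return The auROC, a single number in \[0, 1\].
#' @examples
#' evaluate_auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # 1
#' @export
evaluate_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("auROC needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binary accuracy at a threshold
#'
#' @param scores Probabilities in \[0, 1\].
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Fraction of correct hard calls.
#' @export
binary_accuracy <- function(scores, labels, threshold = 0.5) {
  mean((scores > threshold) == (as.integer(labels) == 1L))
}
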