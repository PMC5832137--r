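check_shapes <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("score/bipartition and truth matrices must have matching shapes")
}

#' Hamming loss
#'
#' Mean fraction of labels in the symmetric difference between predicted
#' and true label sets:
#' \eqn{\mathrm{HL} = \frac{1}{p}\sum_i \frac{1}{Q} |h(x_i) \Delta Y_i|}.
#' Smaller is better; 0 iff the bipartition is exact.
#'
#' @param bipartition binary p x Q prediction matrix.
#' @param truth binary p x Q label matrix.
#' @return value in \[0, 1\].
#' @export
hamming_loss <- function(bipartition, truth) {
  check_shapes(bipartition, truth)
  mean(rowMeans(bipartition != truth))
}

#' One-error
#'
#' Fraction of instances whose single top-ranked label is not relevant.
#' Instances with an empty truth row are excluded with a warning.
#'
#' @param scores p x Q score matrix (ranking function f).
#' @param truth binary p x Q label matrix.
#' @return value in \[0, 1\].
#' @export
one_error <- function(scores, truth) {
  check_shapes(scores, truth)
  rows <- metric_rows(truth, need_neg = FALSE)
  mean(vapply(rows, function(i) {
    top <- which(rank_labels(scores[i, ]) == 1L)
    truth[i, top] != 1
  }, logical(1)))
}

#' Coverage
#'
#' Average search depth down the ranked label list needed to cover all
#' relevant labels, minus one:
#' \eqn{\frac{1}{p}\sum_i \max_{y \in Y_i} \mathrm{rank}_f(x_i, y) - 1}.
#' Ranges from 0 to Q - 1; smaller is better.
#'
#' @inheritParams one_error
#' @return value in \[0, Q-1\].
#' @export
coverage <- function(scores, truth) {
  check_shapes(scores, truth)
  rows <- metric_rows(truth, need_neg = FALSE)
  mean(vapply(rows, function(i) {
    r <- rank_labels(scores[i, ])
    max(r[truth[i, ] == 1])
  }, numeric(1))) - 1
}

#' Ranking loss
#'
#' Fraction of (relevant, irrelevant) label pairs ordered wrongly (ties
#' count as violations):
#' \eqn{\frac{1}{p}\sum_i |\{(y_1,y_2) \in Y_i \times \bar Y_i :
#'   f(x_i,y_1) \le f(x_i,y_2)\}| / (|Y_i||\bar Y_i|)}.
#' Rows with an empty relevant or irrelevant set are excluded with a
#' warning.
#'
#' @inheritParams one_error
#' @return value in \[0, 1\].
#' @export
ranking_loss <- function(scores, truth) {
  check_shapes(scores, truth)
  rows <- metric_rows(truth, need_neg = TRUE)
  mean(vapply(rows, function(i) {
    pos <- scores[i, truth[i, ] == 1]
    neg <- scores[i, truth[i, ] == 0]
    sum(outer(pos, neg, "<=")) / (length(pos) * length(neg))
  }, numeric(1)))
}

#' Average precision (multilabel)
#'
#' Mean over relevant labels of the precision of the ranked list truncated
#' at that label's rank:
#' \eqn{\frac{1}{p}\sum_i \frac{1}{|Y_i|} \sum_{y \in Y_i}
#'   \frac{|\{y' \in Y_i : \mathrm{rank}(x_i,y') \le \mathrm{rank}(x_i,y)\}|}
#'        {\mathrm{rank}(x_i,y)}}.
#' Larger is better; 1 iff every relevant label outranks every irrelevant
#' one.
#'
#' @inheritParams one_error
#' @return value in \[0, 1\].
#' @export
average_precision <- function(scores, truth) {
  check_shapes(scores, truth)
  rows <- metric_rows(truth, need_neg = FALSE)
  mean(vapply(rows, function(i) {
    r <- rank_labels(scores[i, ])
    rel <- r[truth[i, ] == 1]
    mean(vapply(rel, function(rk) sum(rel <= rk) / rk, numeric(1)))
  }, numeric(1)))
}

# rows usable for ranking metrics; warns about excluded degenerate rows
metric_rows <- function(truth, need_neg) {
  ok <- rowSums(truth) >= 1
  if (need_neg) ok <- ok & rowSums(truth) <= ncol(truth) - 1
  if (!all(ok))
    warning(sprintf("%d degenerate row(s) excluded from the metric",
                    sum(!ok)))
  if (!any(ok)) stop("no evaluable rows")
  which(ok)
}

#' All five multilabel measures at once
#' @param scores p x Q score matrix.
#' @param bipartition binary p x Q prediction matrix.
#' @param truth binary p x Q label matrix.
#' @return named numeric vector: `hamming_loss`, `one_error`, `coverage`,
#'   `ranking_loss`, `average_precision`.
#' @export
evaluate_multilabel <- function(scores, bipartition, truth) {
  c(hamming_loss = hamming_loss(bipartition, truth),
    one_error = one_error(scores, truth),
    coverage = coverage(scores, truth),
    ranking_loss = ranking_loss(scores, truth),
    average_precision = average_precision(scores, truth))
}
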