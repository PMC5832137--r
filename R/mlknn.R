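#' Fit a multilabel k-nearest-neighbor model
#'
#' Bayesian per-label prediction from neighbor counts. For each label j the
#' prior is Laplace-smoothed,
#' \deqn{P(H_j) = (s + \sum_i Y_{ij}) / (2s + p),}
#' and the conditionals \eqn{P(E_c \mid H_j)}, \eqn{P(E_c \mid \lnot H_j)}
#' — the probability of seeing exactly c positive neighbors among the k
#' nearest when the label does or does not hold — are estimated from the
#' training set (self excluded from each point's neighbors, Euclidean
#' distance, index-ordered ties).
#'
#' @param X feature matrix (p x d).
#' @param Y binary label matrix (p x Q).
#' @param k neighbor count (k < p); default 10.
#' @param s Laplace smoothing constant; default 1.
#' @return an `mlknn_model`.
#' @export
mlknn_fit <- function(X, Y, k = 10L, s = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- nrow(X)
  stopifnot(nrow(Y) == p, s > 0)
  if (k >= p) stop("k must be smaller than the number of training instances")
  Q <- ncol(Y)

  prior <- (s + colSums(Y)) / (2 * s + p)

  D2 <- euclid2(X, X)
  counts <- matrix(0L, nrow = p, ncol = Q)
  for (i in seq_len(p)) {
    ord <- order(D2[i, ], seq_len(p))
    nb <- setdiff(ord, i)[seq_len(k)]
    counts[i, ] <- colSums(Y[nb, , drop = FALSE])
  }

  # kc1[c+1, j] = # training points with label j and c positive neighbors
  kc1 <- matrix(0, nrow = k + 1L, ncol = Q)
  kc0 <- matrix(0, nrow = k + 1L, ncol = Q)
  for (j in seq_len(Q)) {
    pos <- Y[, j] == 1
    kc1[, j] <- tabulate(counts[pos, j] + 1L, nbins = k + 1L)
    kc0[, j] <- tabulate(counts[!pos, j] + 1L, nbins = k + 1L)
  }
  cond1 <- sweep(s + kc1, 2, s * (k + 1) + colSums(kc1), "/")
  cond0 <- sweep(s + kc0, 2, s * (k + 1) + colSums(kc0), "/")

  structure(list(k = as.integer(k), s = s, prior = prior,
                 cond_pos = cond1, cond_neg = cond0,
                 X = X, Y = Y),
            class = "mlknn_model")
}

euclid2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

#' Posterior label scores for query instances
#'
#' For each query, counts positive neighbors c_j among its k nearest
#' training points and returns the posterior
#' \eqn{P(H_j \mid E_{c_j})} for each label. Bipartition is posterior > 0.5.
#'
#' @param model an `mlknn_model`.
#' @param X query feature matrix (rows are instances).
#' @return list with `scores` (posteriors) and `bipartition`.
#' @export
mlknn_predict <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); Q <- ncol(model$Y); k <- model$k
  D2 <- euclid2(X, model$X)
  S <- matrix(0, nrow = n, ncol = Q)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ], seq_len(nrow(model$X)))[seq_len(k)]
    cc <- colSums(model$Y[nb, , drop = FALSE])
    num <- model$prior * model$cond_pos[cbind(cc + 1L, seq_len(Q))]
    den <- num + (1 - model$prior) * model$cond_neg[cbind(cc + 1L, seq_len(Q))]
    S[i, ] <- num / den
  }
  colnames(S) <- colnames(model$Y)
  list(scores = S, bipartition = (S > 0.5) * 1L)
}

#' @rdname mlknn_predict
#' @param x a single query feature vector.
#' @return `mlknn_score`: the posterior score row for one instance.
#' @export
mlknn_score <- function(model, x) {
  mlknn_predict(model, matrix(x, nrow = 1))$scores[1, ]
}

#' @export
print.mlknn_model <- function(x, ...) {
  cat(sprintf("multilabel kNN: p = %d, Q = %d, k = %d, s = %g\n",
              nrow(x$X), ncol(x$Y), x$k, x$s))
  invisible(x)
}
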