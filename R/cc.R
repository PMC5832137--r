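#' Fit a classifier chain
#'
#' One binary base classifier per label, linked along `chain_order`: the
#' classifier for the j-th chain position is trained on the features
#' augmented with the true labels of all earlier positions, so label
#' dependencies propagate down the chain. A label column with a single
#' class in training yields a constant predictor with a warning.
#'
#' @param X feature matrix (p x d).
#' @param Y binary label matrix (p x Q).
#' @param chain_order a permutation of `1:Q`, or `"asis"` (label-space
#'   order, the default) or `"random"` (seeded).
#' @param base_learner a learner from [make_logistic_learner()] (default).
#' @param seed integer seed (used for `chain_order = "random"`).
#' @return a `cc_model`.
#' @export
cc_fit <- function(X, Y, chain_order = "asis",
                   base_learner = make_logistic_learner(), seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Q <- ncol(Y)
  if (identical(chain_order, "asis")) {
    chain_order <- seq_len(Q)
  } else if (identical(chain_order, "random")) {
    set.seed(seed)
    chain_order <- sample.int(Q)
  }
  stopifnot(length(chain_order) == Q, all(sort(chain_order) == seq_len(Q)))

  fits <- vector("list", Q)
  n_constant <- 0L
  for (pos in seq_len(Q)) {
    j <- chain_order[pos]
    earlier <- chain_order[seq_len(pos - 1L)]
    Xa <- cbind(X, Y[, earlier, drop = FALSE])
    if (length(unique(Y[, j])) < 2L) n_constant <- n_constant + 1L
    fits[[pos]] <- base_learner$fit(Xa, Y[, j])
  }
  if (n_constant > 0L)
    warning(sprintf("%d single-class label column(s) fitted as constant predictors",
                    n_constant))
  structure(list(chain_order = chain_order, fits = fits, Q = Q,
                 base_learner = base_learner, seed = as.integer(seed)),
            class = "cc_model")
}

#' Propagate predictions down a classifier chain
#'
#' Hard 0/1 predictions of earlier chain positions are fed as features to
#' later ones; scores are each classifier's positive-class probability and
#' the bipartition thresholds them at 0.5.
#'
#' @param model a `cc_model`.
#' @param X query feature matrix.
#' @return list with `scores` and `bipartition`, columns in label order.
#' @export
cc_predict <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); Q <- model$Q
  S <- matrix(0, n, Q)
  hard <- matrix(0, n, Q)
  for (pos in seq_len(Q)) {
    j <- model$chain_order[pos]
    earlier <- model$chain_order[seq_len(pos - 1L)]
    Xa <- cbind(X, hard[, earlier, drop = FALSE])
    fit <- model$fits[[pos]]
    if (inherits(fit, "constant_fit")) {
      pr <- rep(as.numeric(fit$constant == "1"), n)
    } else {
      pr <- model$base_learner$predict(fit, Xa, type = "prob")
    }
    S[, j] <- pr
    hard[, j] <- (pr > 0.5) * 1
  }
  list(scores = S, bipartition = hard)
}

#' @rdname cc_predict
#' @param x a single query feature vector.
#' @export
cc_score <- function(model, x) {
  cc_predict(model, matrix(x, nrow = 1))$scores[1, ]
}

#' @export
print.cc_model <- function(x, ...) {
  cat(sprintf("classifier chain over %d labels\n", x$Q))
  invisible(x)
}

#' Rank labels by descending score
#'
#' Rank 1 is the best (highest) score; ties are broken by ascending label
#' index so ranking-based metrics are deterministic.
#'
#' @param score_row finite numeric score row.
#' @return integer rank vector (1 = best).
#' @export
rank_labels <- function(score_row) {
  stopifnot(all(is.finite(score_row)))
  r <- integer(length(score_row))
  r[order(-score_row, seq_along(score_row))] <- seq_along(score_row)
  r
}
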