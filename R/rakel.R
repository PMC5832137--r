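#' Fit a random k-labelsets (label-powerset ensemble) model
#'
#' Draws `m` distinct random labelsets of size `k_r` and trains one
#' label-powerset multiclass base classifier per set: within a set, every
#' observed label combination becomes one class. At prediction time each
#' labelset votes for the labels in its predicted combination; a label's
#' score is the fraction of labelsets containing it that vote positive.
#'
#' @param X feature matrix (p x d).
#' @param Y binary label matrix (p x Q).
#' @param k_r labelset size (1..Q); default 3.
#' @param m number of labelsets; default `2 * Q`, capped by the number of
#'   distinct size-`k_r` subsets (exceeding it is an error).
#' @param base_learner a learner from [make_logistic_learner()] (default).
#' @param seed integer seed for the labelset draw.
#' @return a `rakel_model`.
#' @export
rakel_fit <- function(X, Y, k_r = 3L, m = 2L * ncol(Y),
                      base_learner = make_logistic_learner(), seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Q <- ncol(Y)
  stopifnot(k_r >= 1, k_r <= Q, m >= 1)
  n_distinct <- choose(Q, k_r)
  if (m > n_distinct)
    stop(sprintf("m = %d exceeds the %d distinct labelsets of size %d",
                 m, n_distinct, k_r))

  set.seed(seed)
  sets <- list()
  seen <- character(0)
  while (length(sets) < m) {
    cand <- sort(sample.int(Q, k_r))
    key <- paste(cand, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      sets[[length(sets) + 1L]] <- cand
    }
  }

  uncovered <- setdiff(seq_len(Q), unique(unlist(sets)))
  if (length(uncovered))
    warning(sprintf("%d label(s) covered by no labelset will score 0",
                    length(uncovered)))

  members <- lapply(sets, function(ss) {
    cls <- apply(Y[, ss, drop = FALSE], 1, paste, collapse = "")
    fit <- base_learner$fit(X, cls)
    list(labels = ss, fit = fit)
  })
  structure(list(members = members, Q = Q, k_r = as.integer(k_r),
                 m = as.integer(m), base_learner = base_learner,
                 uncovered = uncovered, seed = as.integer(seed)),
            class = "rakel_model")
}

#' Vote-fraction scores from a labelset ensemble
#'
#' @param model a `rakel_model`.
#' @param X query feature matrix.
#' @return list with `scores` (vote fractions in \[0, 1\]) and
#'   `bipartition` (vote fraction > 0.5).
#' @export
rakel_predict <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X); Q <- model$Q
  votes <- matrix(0, n, Q)
  appearances <- numeric(Q)
  for (mem in model$members) {
    appearances[mem$labels] <- appearances[mem$labels] + 1
    cls <- model$base_learner$predict(mem$fit, X, type = "class")
    bits <- do.call(rbind, strsplit(cls, ""))
    votes[, mem$labels] <- votes[, mem$labels] +
      matrix(as.numeric(bits), nrow = n)
  }
  S <- sweep(votes, 2, pmax(appearances, 1), "/")
  S[, appearances == 0] <- 0
  list(scores = S, bipartition = (S > 0.5) * 1L)
}

#' @rdname rakel_predict
#' @param x a single query feature vector.
#' @export
rakel_score <- function(model, x) {
  rakel_predict(model, matrix(x, nrow = 1))$scores[1, ]
}

#' @export
print.rakel_model <- function(x, ...) {
  cat(sprintf("random %d-labelsets ensemble: m = %d over Q = %d labels\n",
              x$k_r, x$m, x$Q))
  invisible(x)
}
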