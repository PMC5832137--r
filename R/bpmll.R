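#' Pairwise exponential ranking loss for one instance
#'
#' The multilabel backpropagation error
#' \deqn{E_i = \frac{1}{|Y_i||\bar Y_i|}
#'   \sum_{(k,l) \in Y_i \times \bar Y_i} \exp(-(c_k - c_l)),}
#' where \eqn{Y_i} is the relevant label set, \eqn{\bar Y_i} its complement,
#' and \eqn{c} the network output row. Small when every relevant label's
#' output exceeds every irrelevant label's.
#'
#' @param scores_row numeric output row of length Q.
#' @param label_row binary row of length Q with at least one 1 and one 0.
#' @return nonnegative scalar.
#' @export
bpmll_loss <- function(scores_row, label_row) {
  pos <- which(label_row == 1)
  neg <- which(label_row == 0)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("pairwise ranking loss needs at least one relevant and one irrelevant label")
  sum(exp(-scores_row[pos])) * sum(exp(scores_row[neg])) /
    (length(pos) * length(neg))
}

#' Legacy per-instance sum-of-squares loss
#'
#' The classic feed-forward objective \eqn{\sum_j (c_j - d_j)^2} with
#' bipolar targets \eqn{d_j = +1} for relevant and \eqn{-1} for irrelevant
#' labels (tanh outputs). Kept as a reference loss; it treats labels
#' independently, which the pairwise loss was designed to fix.
#'
#' @inheritParams bpmll_loss
#' @return nonnegative scalar.
#' @export
legacy_squared_loss <- function(scores_row, label_row) {
  d <- ifelse(label_row == 1, 1, -1)
  sum((scores_row - d)^2)
}

bpmll_unpack <- function(par, d, m, Q) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * m)], d, m); i <- i + d * m
  b1 <- par[i + seq_len(m)]; i <- i + m
  W2 <- matrix(par[i + seq_len(m * Q)], m, Q); i <- i + m * Q
  b2 <- par[i + seq_len(Q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

bpmll_forward <- function(w, X) {
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  C <- tanh(sweep(H %*% w$W2, 2, w$b2, "+"))
  list(H = H, C = C)
}

# mean pairwise ranking loss over eligible rows + L2 penalty on weights
bpmll_objective <- function(par, X, Y, m, l2) {
  w <- bpmll_unpack(par, ncol(X), m, ncol(Y))
  C <- bpmll_forward(w, X)$C
  losses <- vapply(seq_len(nrow(Y)), function(i)
    bpmll_loss(C[i, ], Y[i, ]), numeric(1))
  mean(losses) + l2 / 2 * (sum(w$W1^2) + sum(w$W2^2))
}

bpmll_gradient <- function(par, X, Y, m, l2) {
  d <- ncol(X); Q <- ncol(Y); n <- nrow(X)
  w <- bpmll_unpack(par, d, m, Q)
  fw <- bpmll_forward(w, X)
  H <- fw$H; C <- fw$C

  Ym <- Y == 1
  nY <- rowSums(Ym); nN <- Q - nY
  A <- exp(-C) * Ym                 # relevant-label terms
  B <- exp(C) * !Ym                 # irrelevant-label terms
  G <- (-A * rowSums(B) + B * rowSums(A)) / (nY * nN)   # dE_i / dC

  dC <- G * (1 - C^2) / n
  dW2 <- t(H) %*% dC + l2 * w$W2
  db2 <- colSums(dC)
  dH <- (dC %*% t(w$W2)) * (1 - H^2)
  dW1 <- t(X) %*% dH + l2 * w$W1
  db1 <- colSums(dH)
  c(as.numeric(dW1), db1, as.numeric(dW2), db2)
}

#' Fit the pairwise-ranking multilabel network
#'
#' A single-hidden-layer feed-forward network (tanh hidden and output
#' units) trained by full-batch gradient descent on the mean pairwise
#' exponential ranking loss ([bpmll_loss()]) plus an L2 weight penalty.
#' Instances whose label row is all-positive or all-negative have an empty
#' pair set and are skipped with a warning. Because the ranking loss fixes
#' only the order of outputs, a bipartition threshold function t(x) is then
#' fitted by linear least squares from training score rows to each row's
#' error-minimizing threshold; prediction marks label j positive when
#' c_j > t(x).
#'
#' @param X feature matrix (p x d).
#' @param Y binary label matrix (p x Q).
#' @param hidden_frac hidden width as a fraction of d (at least 2 units).
#' @param epochs passes over the training set.
#' @param learning_rate step size.
#' @param l2 L2 penalty on weights.
#' @param batch_size instances per stochastic gradient step (instance order
#'   reshuffled each epoch, seeded); 1 is classic per-instance descent,
#'   `Inf` full-batch descent, whose training loss is monotone for small
#'   learning rates. The default 20 trades a little gradient noise for
#'   vectorized speed.
#' @param seed integer seed for weight initialization and shuffling.
#' @return a `bpmll_model`.
#' @export
bpmll_fit <- function(X, Y, hidden_frac = 0.2, epochs = 100L,
                      learning_rate = 0.05, l2 = 1e-5, batch_size = 20,
                      seed = 1L) {
  stopifnot(nrow(X) == nrow(Y))
  X <- as.matrix(X); Y <- as.matrix(Y)
  eligible <- rowSums(Y) >= 1 & rowSums(Y) <= ncol(Y) - 1
  if (!any(eligible)) stop("no instance has both a relevant and an irrelevant label")
  if (!all(eligible))
    warning(sprintf("%d instance(s) with empty pair sets skipped in training",
                    sum(!eligible)))
  # standardize inputs so gradient magnitudes do not depend on feature
  # scale (topic proportions are O(1/K) and would otherwise stall learning)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xe <- Xs[eligible, , drop = FALSE]
  Ye <- Y[eligible, , drop = FALSE]

  d <- ncol(X); Q <- ncol(Y)
  m <- max(2L, ceiling(hidden_frac * d))
  set.seed(seed)
  n_par <- d * m + m + m * Q + Q
  par <- stats::runif(n_par, -0.5, 0.5) / sqrt(d)

  n <- nrow(Xe)
  bs <- if (is.finite(batch_size)) max(1L, as.integer(batch_size)) else n
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    for (start in seq.int(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      g <- bpmll_gradient(par, Xe[idx, , drop = FALSE],
                          Ye[idx, , drop = FALSE], m, l2)
      par <- par - learning_rate * g
    }
    trace[e] <- bpmll_objective(par, Xe, Ye, m, l2)
  }

  w <- bpmll_unpack(par, d, m, Q)
  S <- bpmll_forward(w, Xe)$C
  t_opt <- vapply(seq_len(nrow(S)), function(i)
    optimal_threshold(S[i, ], Ye[i, ]), numeric(1))
  th_fit <- stats::lm.fit(cbind(1, S), t_opt)
  th_fit$coefficients[is.na(th_fit$coefficients)] <- 0
  model <- structure(c(w, list(hidden = m, d = d, Q = Q,
                               center = ctr, scale = scl,
                               threshold_coef = th_fit$coefficients,
                               loss_trace = trace,
                               skipped = sum(!eligible),
                               seed = as.integer(seed))),
                     class = "bpmll_model")
  model
}

# threshold minimizing (#relevant below or at t) + (#irrelevant at or above t);
# midpoint of the optimal segment, deterministic.
optimal_threshold <- function(scores_row, label_row) {
  s <- sort(unique(scores_row))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  errs <- vapply(cand, function(t)
    sum(label_row == 1 & scores_row <= t) +
      sum(label_row == 0 & scores_row >= t), numeric(1))
  cand[which.min(errs)]
}

#' Network output scores (ranking function f)
#' @param model a `bpmll_model`.
#' @param X feature matrix.
#' @return p x Q score matrix in (-1, 1).
#' @export
bpmll_score <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  bpmll_forward(model, Xs)$C
}

#' Scores and thresholded bipartition
#' @param model a `bpmll_model`.
#' @param X feature matrix.
#' @return list with `scores` (p x Q) and `bipartition` (binary p x Q).
#' @export
bpmll_predict <- function(model, X) {
  S <- bpmll_score(model, X)
  t_hat <- drop(cbind(1, S) %*% model$threshold_coef)
  list(scores = S, bipartition = (S > t_hat) * 1L)
}

#' @export
print.bpmll_model <- function(x, ...) {
  cat(sprintf("pairwise-ranking network: %d -> %d -> %d, final loss %.4g\n",
              x$d, x$hidden, x$Q, utils::tail(x$loss_trace, 1)))
  invisible(x)
}
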