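#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Token-topic assignments are resampled for `n_iter` full sweeps from the
#' collapsed conditional
#' \deqn{p(z = k) \propto (C_{dk} + \alpha)\,
#'   \frac{C_{wk} + \beta}{\sum_w C_{wk} + |V|\beta},}
#' with the current token excluded from all counts. Final-state counts are
#' kept (no averaging over a burn-in tail). Deterministic for a fixed seed.
#'
#' @param docs list of integer token-id vectors (1-based), e.g. from
#'   [corpus_documents()].
#' @param K number of topics.
#' @param vocab character vector naming the token ids.
#' @param alpha,beta Dirichlet smoothing hyperparameters; defaults `50 / K`
#'   and `0.01`, common collapsed-Gibbs practice.
#' @param n_iter number of full Gibbs sweeps.
#' @param avg_sweeps number of final sweeps over which the document-topic
#'   estimator is averaged (posterior-mean features); 0 uses the final
#'   state only. Defaults to the last half of the sweeps.
#' @param seed integer seed.
#' @return a `topic_model`: counts `C_dk` (D x K), `C_wk` (W x K), topic
#'   totals, assignments, document lengths, the sweep-averaged
#'   document-topic matrix (`theta_mean`, when requested), and the
#'   hyperparameters.
#' @export
fit_lda <- function(docs, K, vocab, alpha = 50 / K, beta = 0.01,
                    n_iter = 500L, avg_sweeps = n_iter %/% 2L, seed = 1L) {
  stopifnot(K >= 1, alpha > 0, beta > 0, length(docs) >= 1)
  W <- length(vocab)
  if (W == 0L) stop("empty vocabulary")
  D <- length(docs)
  lens <- lengths(docs)
  tokens <- unlist(docs, use.names = FALSE)
  if (length(tokens) == 0L) stop("corpus contains no tokens")
  stopifnot(all(tokens >= 1L), all(tokens <= W))
  doc_id <- rep.int(seq_len(D), lens)
  avg_sweeps <- min(as.integer(avg_sweeps), as.integer(n_iter))

  set.seed(seed)
  z0 <- sample.int(K, length(tokens), replace = TRUE)
  res <- gibbs_lda_sweeps(tokens - 1L, doc_id - 1L, z0 - 1L,
                          as.integer(K), as.integer(W), as.integer(D),
                          alpha, beta, as.integer(n_iter), avg_sweeps)
  z <- res$z + 1L

  C_dk <- counts_from_assignments(doc_id, z, D, K)
  C_wk <- counts_from_assignments(tokens, z, W, K)
  rownames(C_wk) <- vocab
  theta_mean <- if (avg_sweeps > 0L) res$theta_sum / avg_sweeps else NULL
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 C_dk = C_dk, C_wk = C_wk,
                 topic_totals = colSums(C_wk),
                 vocab = vocab, assignments = z,
                 doc_lengths = lens, theta_mean = theta_mean,
                 avg_sweeps = avg_sweeps, seed = as.integer(seed)),
            class = "topic_model")
}

counts_from_assignments <- function(row_id, z, n_rows, K) {
  m <- matrix(0L, nrow = n_rows, ncol = K)
  tab <- table(factor(row_id, levels = seq_len(n_rows)),
               factor(z, levels = seq_len(K)))
  m[] <- as.integer(tab)
  m
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic model: K = %d, D = %d, |V| = %d, alpha = %.4g, beta = %.4g\n",
              x$K, nrow(x$C_dk), length(x$vocab), x$alpha, x$beta))
  invisible(x)
}

#' Document-topic probability features
#'
#' Smoothed topic proportions
#' \eqn{p(k \mid d) = (C_{dk} + \alpha) / (\sum_k C_{dk} + K\alpha)};
#' each row sums to 1 and is the feature vector used by the classifiers.
#' When the model was fitted with sweep averaging (`avg_sweeps > 0`), the
#' estimator averaged over the final sweeps is returned (a lower-variance
#' estimate of the same posterior mean); `use_mean = FALSE` forces the
#' final-state estimator.
#'
#' @param model a `topic_model`.
#' @param d optional document index; default returns the full D x K matrix.
#' @param use_mean use the sweep-averaged estimator when available.
#' @return probability vector of length K, or a D x K matrix.
#' @export
doc_topic_features <- function(model, d = NULL, use_mean = TRUE) {
  theta <- if (use_mean && !is.null(model$theta_mean)) {
    model$theta_mean
  } else {
    (model$C_dk + model$alpha) /
      (rowSums(model$C_dk) + model$K * model$alpha)
  }
  colnames(theta) <- sprintf("topic_%d", seq_len(model$K) - 1L)
  if (is.null(d)) theta else theta[d, ]
}

#' Topic-word probability distribution
#'
#' Smoothed word distribution of topic `k`:
#' \eqn{p(w \mid k) = (C_{wk} + \beta) / (\sum_w C_{wk} + |V|\beta)},
#' normalized over the vocabulary.
#'
#' @param model a `topic_model`.
#' @param k topic index (1-based).
#' @return probability vector over the vocabulary.
#' @export
topic_word_dist <- function(model, k) {
  stopifnot(k >= 1, k <= model$K)
  phi <- (model$C_wk[, k] + model$beta) /
    (model$topic_totals[k] + length(model$vocab) * model$beta)
  stats::setNames(phi, model$vocab)
}

#' Fold in held-out documents under a fitted topic model
#'
#' Resamples topic assignments for new documents while holding the fitted
#' word-topic counts fixed, then returns smoothed document-topic features.
#' This is how test-fold records obtain topic features without leaking their
#' tokens into the fit.
#'
#' @param model a `topic_model`.
#' @param docs list of integer token-id vectors over `model$vocab` (ids
#'   outside the vocabulary must already be dropped).
#' @param n_iter fold-in Gibbs sweeps.
#' @param avg_sweeps sweeps averaged for the returned estimator, as in
#'   [fit_lda()].
#' @param seed integer seed.
#' @return matrix of document-topic features, one row per document.
#' @export
infer_doc_topics <- function(model, docs, n_iter = 50L,
                             avg_sweeps = n_iter %/% 2L, seed = 1L) {
  D <- length(docs)
  K <- model$K
  out <- matrix(1 / K, nrow = D, ncol = K,
                dimnames = list(NULL, sprintf("topic_%d", seq_len(K) - 1L)))
  lens <- lengths(docs)
  nonempty <- which(lens > 0L)
  avg_sweeps <- min(as.integer(avg_sweeps), as.integer(n_iter))
  if (length(nonempty)) {
    tokens <- unlist(docs[nonempty], use.names = FALSE)
    doc_id <- rep.int(seq_along(nonempty), lens[nonempty])
    set.seed(seed)
    z0 <- sample.int(K, length(tokens), replace = TRUE)
    res <- gibbs_lda_foldin(tokens - 1L, doc_id - 1L, z0 - 1L,
                            model$C_wk, as.integer(model$topic_totals),
                            as.integer(K), length(model$vocab),
                            length(nonempty),
                            model$alpha, model$beta, as.integer(n_iter),
                            avg_sweeps)
    if (avg_sweeps > 0L) {
      out[nonempty, ] <- res$theta_sum / avg_sweeps
    } else {
      C_dk <- counts_from_assignments(doc_id, res$z + 1L,
                                      length(nonempty), K)
      out[nonempty, ] <- (C_dk + model$alpha) /
        (rowSums(C_dk) + K * model$alpha)
    }
  }
  out
}

#' Corpus log-likelihood under the current topic-model state
#'
#' Sum over tokens of \eqn{\log \sum_k p(k \mid d)\, p(w \mid k)} with the
#' smoothed estimators. Used to monitor the Gibbs trend; it is not a
#' marginal likelihood.
#'
#' @param model a `topic_model`.
#' @param docs the documents the model was fitted on.
#' @return scalar log-likelihood.
#' @export
lda_log_likelihood <- function(model, docs) {
  theta <- doc_topic_features(model)
  phi <- vapply(seq_len(model$K), function(k) topic_word_dist(model, k),
                numeric(length(model$vocab)))        # W x K
  ll <- 0
  for (d in seq_along(docs)) {
    if (length(docs[[d]]) == 0L) next
    probs <- phi[docs[[d]], , drop = FALSE] %*% theta[d, ]
    ll <- ll + sum(log(probs))
  }
  ll
}

#' Write a feature matrix as delimited text with a header row
#' @param features numeric matrix with column names.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
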