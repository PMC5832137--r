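#' Build (center, context) training pairs with a symmetric window
#'
#' For every position t and every offset j with -c <= j <= c, j != 0, the
#' pair (w_t, w_{t+j}) is emitted, clipped at document boundaries.
#'
#' @param docs list of integer token-id vectors (1-based).
#' @param window context half-width c.
#' @return two-column integer matrix (`center`, `context`).
#' @export
skipgram_pairs <- function(docs, window) {
  stopifnot(window >= 1)
  out <- lapply(docs, function(d) {
    n <- length(d)
    if (n < 2L) return(NULL)
    centers <- integer(0); contexts <- integer(0)
    for (j in seq_len(window)) {
      if (j >= n) break
      lead <- seq_len(n - j)
      centers <- c(centers, d[lead], d[lead + j])
      contexts <- c(contexts, d[lead + j], d[lead])
    }
    cbind(center = centers, context = contexts)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L)
    stop("no skip-gram training pairs: window larger than every document")
  out
}

#' Train skip-gram word vectors
#'
#' Maximizes the average log conditional probability of context words given
#' center words over a symmetric window of half-width `window`. With
#' `n_negative = 0` the exact softmax over the vocabulary is used with
#' full-batch gradient ascent (feasible at small vocabulary sizes, and the
#' objective is then monotone for small learning rates); with
#' `n_negative > 0`, stochastic gradient ascent with negative sampling
#' (unigram^0.75 noise distribution) approximates it. Deterministic for a
#' fixed seed.
#'
#' @param docs list of integer token-id vectors (1-based), e.g. from
#'   [corpus_documents()].
#' @param vocab character vector naming the token ids.
#' @param dim embedding dimension T.
#' @param window context half-width; default 5.
#' @param epochs passes over the training pairs; default 5.
#' @param learning_rate initial step size (linear decay); default 0.025.
#' @param n_negative negative samples per positive pair; 0 selects the
#'   exact-softmax path.
#' @param seed integer seed.
#' @return an `embedding_model` with `input_vectors` and `output_vectors`
#'   (both W x T), the vocabulary, and the training objective trace.
#' @export
fit_skipgram <- function(docs, vocab, dim, window = 5L, epochs = 5L,
                         learning_rate = 0.025, n_negative = 5L, seed = 1L) {
  stopifnot(dim >= 1, epochs >= 1, learning_rate > 0, n_negative >= 0)
  W <- length(vocab)
  if (W == 0L) stop("empty vocabulary")
  pairs <- skipgram_pairs(docs, window)

  set.seed(seed)
  vin <- matrix(stats::runif(W * dim, -0.5, 0.5) / dim, nrow = W)
  vout <- matrix(0, nrow = W, ncol = dim)
  trace <- numeric(epochs)

  if (n_negative == 0L) {
    for (e in seq_len(epochs)) {
      g <- softmax_gradient(vin, vout, pairs)
      vin <- vin + learning_rate * g$grad_in
      vout <- vout + learning_rate * g$grad_out
      trace[e] <- softmax_objective(vin, vout, pairs)
    }
  } else {
    counts <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = W)
    wts <- counts^0.75
    neg_cdf <- cumsum(wts / sum(wts))
    total <- as.double(nrow(pairs)) * epochs
    done <- 0
    vin_t <- t(vin)     # T x W: contiguous per-word columns for the kernel
    vout_t <- t(vout)
    for (e in seq_len(epochs)) {
      trace[e] <- sgns_epoch(vin_t, vout_t, pairs[, 1] - 1L, pairs[, 2] - 1L,
                             neg_cdf, as.integer(n_negative),
                             learning_rate, learning_rate * 1e-4,
                             total, done, as.integer(seed) + e)
      done <- done + nrow(pairs)
    }
    vin <- t(vin_t)
    vout <- t(vout_t)
  }
  rownames(vin) <- rownames(vout) <- vocab
  structure(list(vocab = vocab, dim = as.integer(dim),
                 window = as.integer(window),
                 input_vectors = vin, output_vectors = vout,
                 n_negative = as.integer(n_negative),
                 objective_trace = trace, seed = as.integer(seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("skip-gram embeddings: |V| = %d, dim = %d, window = %d\n",
              length(x$vocab), x$dim, x$window))
  invisible(x)
}

#' Exact softmax conditional probability p(w_O | w_I)
#'
#' \deqn{p(w_O \mid w_I) = \frac{\exp({v'_{w_O}}^\top v_{w_I})}
#'   {\sum_{w=1}^{W} \exp({v'_w}^\top v_{w_I})}.}
#'
#' @param model an `embedding_model`.
#' @param w_I,w_O center and context words (strings in the vocabulary).
#' @return probability in (0, 1); over all `w_O` the values sum to 1.
#' @export
softmax_prob <- function(model, w_I, w_O) {
  i <- match(w_I, model$vocab)
  o <- match(w_O, model$vocab)
  if (is.na(i) || is.na(o))
    stop(sprintf("word not in vocabulary: %s",
                 paste(c(w_I, w_O)[is.na(c(i, o))], collapse = ", ")))
  logits <- drop(model$output_vectors %*% model$input_vectors[i, ])
  logits <- logits - max(logits)
  unname(exp(logits[o]) / sum(exp(logits)))
}

# mean log softmax probability over pairs (the training objective, Eq-style
# average); vin/vout are W x T.
softmax_objective <- function(vin, vout, pairs) {
  logits <- vin[pairs[, 1], , drop = FALSE] %*% t(vout)   # P x W
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  sel <- logits[cbind(seq_len(nrow(pairs)), pairs[, 2])]
  mean(sel - lse)
}

# analytic gradient of softmax_objective w.r.t. vin and vout
softmax_gradient <- function(vin, vout, pairs) {
  P <- nrow(pairs)
  W <- nrow(vin)
  logits <- vin[pairs[, 1], , drop = FALSE] %*% t(vout)   # P x W
  m <- apply(logits, 1, max)
  probs <- exp(logits - m)
  probs <- probs / rowSums(probs)                          # P x W
  resid <- -probs
  resid[cbind(seq_len(P), pairs[, 2])] <-
    resid[cbind(seq_len(P), pairs[, 2])] + 1               # P x W

  grad_in <- matrix(0, nrow = W, ncol = ncol(vin))
  gi <- resid %*% vout                                     # P x T
  for (p in seq_len(P))
    grad_in[pairs[p, 1], ] <- grad_in[pairs[p, 1], ] + gi[p, ]

  center_onehot <- matrix(0, nrow = P, ncol = W)
  center_onehot[cbind(seq_len(P), pairs[, 1])] <- 1
  grad_out <- t(resid) %*% (center_onehot %*% vin)         # W x T
  list(grad_in = grad_in / P, grad_out = grad_out / P)
}

#' Document vector by averaging word vectors
#'
#' Arithmetic mean of the input vectors of in-vocabulary tokens;
#' out-of-vocabulary tokens are skipped. An empty or all-out-of-vocabulary
#' document yields the zero vector with a warning.
#'
#' @param model an `embedding_model`.
#' @param tokens character vector of tokens.
#' @return numeric vector of length `model$dim`.
#' @export
doc_vector <- function(model, tokens) {
  ids <- match(tokens, model$vocab)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) {
    warning("document has no in-vocabulary tokens; zero vector returned")
    return(numeric(model$dim))
  }
  colMeans(model$input_vectors[ids, , drop = FALSE])
}

#' Document-vector feature matrix for a corpus
#' @param model an `embedding_model`.
#' @param corpus list of records.
#' @return matrix with one row per record and `model$dim` columns.
#' @export
doc_vector_features <- function(model, corpus) {
  out <- t(vapply(corpus, function(rec)
    suppressWarnings(doc_vector(model, record_tokens(rec))),
    numeric(model$dim)))
  colnames(out) <- sprintf("dim_%d", seq_len(model$dim) - 1L)
  out
}

#' Write / read embeddings in word2vec text format
#'
#' First line "W T", then one line per word: the word followed by T floats.
#'
#' @param model an `embedding_model`.
#' @param path output path.
#' @return `path` invisibly (write); an `embedding_model` with zero output
#'   vectors (read; the text format stores input vectors only).
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(model$vocab), model$dim), con)
  for (i in seq_along(model$vocab))
    writeLines(paste(model$vocab[i],
                     paste(sprintf("%.17g", model$input_vectors[i, ]),
                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  W <- hdr[1]; T_dim <- hdr[2]
  vocab <- character(W)
  vin <- matrix(0, nrow = W, ncol = T_dim)
  for (i in seq_len(W)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    vocab[i] <- parts[1]
    vin[i, ] <- as.numeric(parts[-1])
  }
  rownames(vin) <- vocab
  structure(list(vocab = vocab, dim = T_dim, window = NA_integer_,
                 input_vectors = vin,
                 output_vectors = matrix(0, W, T_dim,
                                         dimnames = list(vocab, NULL)),
                 n_negative = NA_integer_, objective_trace = numeric(0),
                 seed = NA_integer_),
            class = "embedding_model")
}
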