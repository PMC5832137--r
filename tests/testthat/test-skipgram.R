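test_that("pair construction respects the window and rejects empty sets", {
  pairs <- skipgram_pairs(list(c(1L, 2L, 3L)), window = 1)
  expect_equal(nrow(pairs), 4)  # (1,2),(2,1),(2,3),(3,2)
  expect_setequal(paste(pairs[, 1], pairs[, 2]),
                  c("1 2", "2 1", "2 3", "3 2"))
  expect_error(skipgram_pairs(list(1L), window = 2), "no skip-gram")
})

test_that("softmax probability matches its closed form", {
  model <- structure(list(vocab = c("a", "b"), dim = 1L, window = 1L,
                          input_vectors = matrix(c(1, 0), 2, 1,
                                                 dimnames = list(c("a", "b"), NULL)),
                          output_vectors = matrix(c(1, 0), 2, 1,
                                                  dimnames = list(c("a", "b"), NULL)),
                          n_negative = 0L, objective_trace = numeric(0),
                          seed = 1L),
                     class = "embedding_model")
  # logits for center "a": (1, 0) -> p(a|a) = e/(e+1)
  expect_equal(softmax_prob(model, "a", "a"), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  # zero vectors: uniform 1/W
  model$input_vectors[] <- 0
  expect_equal(softmax_prob(model, "a", "b"), 0.5)
  expect_error(softmax_prob(model, "zz", "a"), "vocabulary")
})

test_that("softmax probabilities over contexts sum to one", {
  set.seed(12)
  W <- 6; T_dim <- 4
  model <- structure(list(vocab = letters[1:W], dim = T_dim, window = 2L,
                          input_vectors = matrix(rnorm(W * T_dim), W, T_dim,
                                                 dimnames = list(letters[1:W], NULL)),
                          output_vectors = matrix(rnorm(W * T_dim), W, T_dim,
                                                  dimnames = list(letters[1:W], NULL)),
                          n_negative = 0L, objective_trace = numeric(0),
                          seed = 1L),
                     class = "embedding_model")
  tot <- sum(vapply(letters[1:W], function(o)
    softmax_prob(model, "c", o), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("exact-softmax gradient passes a finite-difference check", {
  docs <- list(c(1L, 2L, 3L, 4L, 5L), c(2L, 5L, 1L))
  pairs <- skipgram_pairs(docs, window = 2)
  set.seed(5)
  vin <- matrix(rnorm(15) * 0.2, 5, 3)
  vout <- matrix(rnorm(15) * 0.2, 5, 3)
  gr <- mldx:::softmax_gradient(vin, vout, pairs)
  h <- 1e-6
  check <- function(M, other, which_in) {
    fd <- matrix(0, nrow(M), ncol(M))
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
      Mp <- M; Mp[i, j] <- M[i, j] + h
      Mm <- M; Mm[i, j] <- M[i, j] - h
      fd[i, j] <- if (which_in)
        (mldx:::softmax_objective(Mp, other, pairs) -
           mldx:::softmax_objective(Mm, other, pairs)) / (2 * h)
      else
        (mldx:::softmax_objective(other, Mp, pairs) -
           mldx:::softmax_objective(other, Mm, pairs)) / (2 * h)
    }
    fd
  }
  fdi <- check(vin, vout, TRUE)
  fdo <- check(vout, vin, FALSE)
  expect_lt(max(abs(gr$grad_in - fdi)) / max(abs(fdi)), 1e-5)
  expect_lt(max(abs(gr$grad_out - fdo)) / max(abs(fdo)), 1e-5)
})

test_that("exact-softmax training objective is non-decreasing", {
  docs <- list(c(1L, 2L, 1L, 2L, 3L), c(3L, 4L, 3L, 4L), c(1L, 2L, 3L, 4L))
  em <- fit_skipgram(docs, vocab = letters[1:4], dim = 3, window = 1,
                     epochs = 30, learning_rate = 0.1, n_negative = 0,
                     seed = 2)
  expect_true(all(diff(em$objective_trace) > -1e-10))
})

test_that("training separates co-occurrence clusters", {
  # two disjoint word communities; within-cluster cosine must win
  set.seed(9)
  docs <- c(replicate(40, sample(1:5, 8, replace = TRUE), simplify = FALSE),
            replicate(40, sample(6:10, 8, replace = TRUE), simplify = FALSE))
  em <- fit_skipgram(docs, vocab = sprintf("w%02d", 1:10), dim = 8,
                     window = 2, epochs = 12, learning_rate = 0.05,
                     n_negative = 0, seed = 3)
  V <- em$input_vectors / sqrt(rowSums(em$input_vectors^2))
  cos <- V %*% t(V)
  within <- c(cos[1:5, 1:5][lower.tri(matrix(0, 5, 5))],
              cos[6:10, 6:10][lower.tri(matrix(0, 5, 5))])
  between <- as.numeric(cos[1:5, 6:10])
  expect_gt(mean(within), mean(between))
})

test_that("negative-sampling path trains, improves, and is reproducible", {
  set.seed(14)
  docs <- c(replicate(30, sample(1:6, 10, replace = TRUE), simplify = FALSE),
            replicate(30, sample(7:12, 10, replace = TRUE), simplify = FALSE))
  vocab <- sprintf("w%02d", 1:12)
  em1 <- fit_skipgram(docs, vocab, dim = 6, window = 2, epochs = 5,
                      n_negative = 5, seed = 4)
  em2 <- fit_skipgram(docs, vocab, dim = 6, window = 2, epochs = 5,
                      n_negative = 5, seed = 4)
  expect_identical(em1, em2)
  expect_gt(utils::tail(em1$objective_trace, 1), em1$objective_trace[1])
})

test_that("document vectors average input vectors and handle OOV", {
  vin <- rbind(c(1, 0), c(0, 1), c(2, 1))
  rownames(vin) <- c("a", "b", "c")
  model <- structure(list(vocab = c("a", "b", "c"), dim = 2L, window = 1L,
                          input_vectors = vin,
                          output_vectors = vin * 0,
                          n_negative = 0L, objective_trace = numeric(0),
                          seed = 1L),
                     class = "embedding_model")
  expect_equal(unname(doc_vector(model, "a")), c(1, 0))
  expect_equal(unname(doc_vector(model, c("a", "b", "c"))), c(1, 2 / 3))
  # opposite vectors cancel
  model$input_vectors <- rbind(a = c(1, 1), b = c(-1, -1), c = c(0, 0))
  expect_equal(unname(doc_vector(model, c("a", "b"))), c(0, 0))
  expect_warning(z <- doc_vector(model, c("zz", "qq")), "no in-vocabulary")
  expect_equal(z, c(0, 0))
})

test_that("word2vec text serialization round-trips input vectors", {
  fix <- small_corpus_fixture(n_records = 30, n_labels = 5, vocab_size = 60,
                              seed = 8)
  dd <- corpus_documents(fix$corpus)
  em <- fit_skipgram(dd$docs, dd$vocab, dim = 4, epochs = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".vec")
  write_embeddings(em, path)
  back <- read_embeddings(path)
  expect_equal(back$vocab, em$vocab)
  expect_equal(back$input_vectors, em$input_vectors, tolerance = 1e-15)
})
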