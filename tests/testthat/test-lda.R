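test_that("single-topic model is degenerate and counts are conserved", {
  docs <- list(c(1L, 2L, 3L), c(2L, 2L), c(3L))
  tm <- fit_lda(docs, K = 1, vocab = c("a", "b", "c"), n_iter = 5, seed = 1)
  expect_true(all(tm$assignments == 1L))
  expect_equal(unname(doc_topic_features(tm)[, 1]), rep(1, 3))

  tm2 <- fit_lda(docs, K = 3, vocab = c("a", "b", "c"), n_iter = 10, seed = 2)
  # doc-topic rows sum to the document token counts
  expect_equal(unname(rowSums(tm2$C_dk)), lengths(docs))
  # word-topic columns sum to tokens assigned per topic
  expect_equal(unname(colSums(tm2$C_wk)),
               unname(tabulate(tm2$assignments, nbins = 3)))
})

test_that("zero-iteration fit keeps the random initialization bookkeeping", {
  tm <- fit_lda(list(c(1L)), K = 4, vocab = letters[1:2], n_iter = 0, seed = 9)
  expect_equal(sum(tm$C_dk), 1L)
  expect_equal(sum(tm$C_wk), 1L)
  expect_equal(which(tm$C_wk[1, ] == 1L), tm$assignments)
})

test_that("document-topic features follow the smoothed estimator", {
  tm <- structure(list(K = 2L, alpha = 1, beta = 0.01,
                       C_dk = matrix(c(2L, 0L), 1, 2),
                       C_wk = matrix(0L, 3, 2),
                       topic_totals = c(0, 0), vocab = letters[1:3],
                       assignments = integer(0), doc_lengths = 2L,
                       seed = 1L),
                  class = "topic_model")
  expect_equal(unname(doc_topic_features(tm, 1)), c(3 / 4, 1 / 4))

  # all-zero counts: uniform
  tm$C_dk <- matrix(0L, 1, 2)
  expect_equal(unname(doc_topic_features(tm, 1)), c(1 / 2, 1 / 2))
})

test_that("topic-word distribution normalizes over the vocabulary", {
  tm <- structure(list(K = 2L, alpha = 1, beta = 0.5,
                       C_dk = matrix(0L, 1, 2),
                       C_wk = matrix(c(3L, 1L, 0L, 0L, 0L, 0L), 3, 2),
                       topic_totals = c(4, 0), vocab = letters[1:3],
                       assignments = integer(0), doc_lengths = 0L,
                       seed = 1L),
                  class = "topic_model")
  phi <- topic_word_dist(tm, 1)
  expect_equal(unname(phi), c(3.5, 1.5, 0.5) / 5.5)
  # zero counts: uniform over vocab
  expect_equal(unname(topic_word_dist(tm, 2)), rep(1 / 3, 3))
  # beta -> 0 limit concentrates on the observed word
  tm$beta <- 1e-12
  tm$C_wk <- matrix(c(1L, 0L, 0L, 0L, 0L, 0L), 3, 2)
  tm$topic_totals <- c(1, 0)
  expect_equal(unname(topic_word_dist(tm, 1))[1], 1, tolerance = 1e-9)
})

test_that("fitted distributions are normalized and reproducible", {
  fix <- small_corpus_fixture(n_records = 60, n_labels = 6, vocab_size = 120,
                              seed = 4)
  dd <- corpus_documents(fix$corpus)
  tm <- fit_lda(dd$docs, K = 5, vocab = dd$vocab, n_iter = 30, seed = 10)
  theta <- doc_topic_features(tm)
  expect_true(max(abs(rowSums(theta) - 1)) < 1e-12)
  for (k in 1:5)
    expect_equal(sum(topic_word_dist(tm, k)), 1, tolerance = 1e-12)

  tm2 <- fit_lda(dd$docs, K = 5, vocab = dd$vocab, n_iter = 30, seed = 10)
  expect_identical(tm, tm2)
})

test_that("gibbs conditional matches enumeration on a 2-word 2-topic toy", {
  # one document, two tokens of different words, K = 2: after many sweeps
  # the chain visits assignment states with the collapsed posterior mass.
  # Enumerate the 4 states exactly and compare occupancy of token 1's topic.
  alpha <- 0.5; beta <- 0.5; W <- 2
  states <- expand.grid(z1 = 1:2, z2 = 1:2)
  joint <- apply(states, 1, function(st) {
    # collapsed joint: prod over tokens of (C_dk^- + a)(C_wk^- + b)/(C_k^- + Wb)
    z <- as.integer(st)
    p <- 1
    cdk <- c(0, 0); cwk <- matrix(0, 2, 2); ck <- c(0, 0)
    for (t in 1:2) {
      w <- t  # token t is word t
      p <- p * (cdk[z[t]] + alpha) * (cwk[w, z[t]] + beta) / (ck[z[t]] + W * beta)
      cdk[z[t]] <- cdk[z[t]] + 1
      cwk[w, z[t]] <- cwk[w, z[t]] + 1
      ck[z[t]] <- ck[z[t]] + 1
    }
    p
  })
  joint <- joint / sum(joint)
  p_z1_is_1 <- sum(joint[states$z1 == 1])

  # long-run Gibbs occupancy
  set.seed(123)
  hits <- 0L
  n_samples <- 4000L
  z <- c(0L, 0L)   # kernel state is 0-based
  for (s in seq_len(n_samples)) {
    z <- mldx:::gibbs_lda_sweeps(c(0L, 1L), c(0L, 0L), z, 2L, 2L, 1L,
                                 alpha, beta, 1L, 0L)$z
    hits <- hits + (z[1] == 0L)
  }
  expect_lt(abs(hits / n_samples - p_z1_is_1), 0.05)
})

test_that("log-likelihood trend is non-decreasing over sweeps", {
  fix <- small_corpus_fixture(n_records = 80, n_labels = 6, vocab_size = 150,
                              seed = 6)
  dd <- corpus_documents(fix$corpus)
  lls <- vapply(c(1, 5, 20, 60), function(ni) {
    tm <- fit_lda(dd$docs, K = 6, vocab = dd$vocab, n_iter = ni, seed = 3)
    lda_log_likelihood(tm, dd$docs)
  }, numeric(1))
  # smoothed monotone trend: later checkpoints dominate the first
  expect_true(all(lls[-1] > lls[1]))
  expect_gt(lls[4], lls[2])
})

test_that("planted topics are recovered on well-separated synthetic data", {
  cfg <- synthetic_config(n_records = 1000, n_labels = 3, n_topics_true = 3,
                          vocab_size = 300, dirichlet_beta = 0.05,
                          cardinality_dist = c(1, 0, 0), seed = 42)
  gen <- generate_corpus(cfg)
  dd <- corpus_documents(gen$corpus)
  tm <- fit_lda(dd$docs, K = 3, vocab = dd$vocab, alpha = 1, n_iter = 300,
                seed = 8)
  phi <- t(vapply(1:3, function(k) topic_word_dist(tm, k),
                  numeric(length(dd$vocab))))
  truth <- gen$truth$topic_word_true[, dd$vocab]
  # best topic permutation by total-variation distance
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  tv <- apply(perms, 1, function(pp)
    mean(vapply(1:3, function(k) 0.5 * sum(abs(phi[pp[k], ] - truth[k, ])),
                numeric(1))))
  expect_lt(min(tv), 0.1)
})
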