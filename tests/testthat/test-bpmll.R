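test_that("pairwise ranking loss matches hand arithmetic", {
  expect_equal(bpmll_loss(c(0.5, 0.5), c(1, 0)), 1)         # equal outputs
  expect_equal(bpmll_loss(c(2, 0), c(1, 0)), exp(-2), tolerance = 1e-12)
  # monotone decreasing in every margin
  margins <- seq(-2, 4, by = 0.5)
  losses <- vapply(margins, function(m) bpmll_loss(c(m, 0), c(1, 0)),
                   numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_lt(bpmll_loss(c(50, 0), c(1, 0)), 1e-20)
  expect_error(bpmll_loss(c(1, 2), c(1, 1)), "irrelevant")
})

test_that("legacy squared loss uses bipolar targets", {
  expect_equal(legacy_squared_loss(c(1, -1), c(1, 0)), 0)
  expect_equal(legacy_squared_loss(c(0, 0), c(1, 0)), 2)
})

test_that("ranking-loss gradient passes a finite-difference check", {
  set.seed(42)
  X <- matrix(rnorm(15), 3, 5)
  Y <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 0), c(1, 1, 0, 1))
  m <- 3
  npar <- 5 * m + m + m * 4 + 4
  par <- runif(npar, -0.5, 0.5)
  g <- mldx:::bpmll_gradient(par, X, Y, m, 1e-5)
  fd <- vapply(seq_len(npar), function(i) {
    e <- numeric(npar); e[i] <- 1e-6
    (mldx:::bpmll_objective(par + e, X, Y, m, 1e-5) -
       mldx:::bpmll_objective(par - e, X, Y, m, 1e-5)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
})

test_that("full-batch training loss is non-increasing at small steps", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  Y <- matrix(rbinom(30, 1, 0.4), 10, 3)
  Y[rowSums(Y) == 0, 1] <- 1
  Y[rowSums(Y) == 3, 3] <- 0
  fit <- bpmll_fit(X, Y, epochs = 40, learning_rate = 0.01,
                   batch_size = Inf, seed = 2)
  expect_true(all(diff(fit$loss_trace) < 1e-10))
})

test_that("instances with empty pair sets are skipped with a warning", {
  X <- matrix(rnorm(12), 4, 3)
  Y <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_warning(fit <- bpmll_fit(X, Y, epochs = 5, seed = 1), "skipped")
  expect_equal(fit$skipped, 2L)
  Yall <- rbind(c(1, 1), c(0, 0))
  expect_error(suppressWarnings(bpmll_fit(X[1:2, ], Yall, epochs = 2)),
               "no instance")
})

test_that("bipartition is consistent with scores and the threshold rule", {
  fix <- small_corpus_fixture(n_records = 120, n_labels = 8, seed = 23)
  dd <- corpus_documents(fix$corpus)
  tm <- fit_lda(dd$docs, K = 8, vocab = dd$vocab, n_iter = 60, seed = 2)
  X <- doc_topic_features(tm)
  fit <- suppressWarnings(bpmll_fit(X, fix$Y, epochs = 40, seed = 3))
  pred <- bpmll_predict(fit, X)
  t_hat <- drop(cbind(1, pred$scores) %*% fit$threshold_coef)
  expect_identical(pred$bipartition, (pred$scores > t_hat) * 1L)
})

test_that("training detects planted signal better than an untrained net", {
  fix <- small_corpus_fixture(n_records = 150, n_labels = 8, seed = 29)
  dd <- corpus_documents(fix$corpus)
  tm <- fit_lda(dd$docs, K = 8, vocab = dd$vocab, n_iter = 80, seed = 2)
  X <- doc_topic_features(tm)
  trained <- suppressWarnings(bpmll_fit(X, fix$Y, epochs = 60, seed = 3))
  untrained <- suppressWarnings(bpmll_fit(X, fix$Y, epochs = 0, seed = 3))
  rl_trained <- suppressWarnings(ranking_loss(bpmll_score(trained, X), fix$Y))
  rl_untrained <- suppressWarnings(ranking_loss(bpmll_score(untrained, X), fix$Y))
  expect_lt(rl_trained, rl_untrained)
})

test_that("fits are bit-reproducible for a fixed seed", {
  set.seed(1)
  X <- matrix(rnorm(60), 15, 4)
  Y <- matrix(rbinom(45, 1, 0.5), 15, 3)
  Y[rowSums(Y) == 0, 2] <- 1
  Y[rowSums(Y) == 3, 1] <- 0
  f1 <- bpmll_fit(X, Y, epochs = 10, seed = 7)
  f2 <- bpmll_fit(X, Y, epochs = 10, seed = 7)
  expect_identical(f1, f2)
})
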