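toy_multilabel <- function(n = 60, seed = 41) {
  # two feature clusters; label 1 tracks cluster A, label 2 cluster B,
  # label 3 = label 1 (deterministic copy), label 4 rare
  set.seed(seed)
  cl <- rep(c(0, 1), length.out = n)
  X <- cbind(cl * 4 + rnorm(n, sd = 0.3), -cl * 4 + rnorm(n, sd = 0.3),
             rnorm(n, sd = 0.3))
  Y <- cbind(1L - cl, cl, 1L - cl, rep(c(1L, 0L, 0L), length.out = n))
  Y[rowSums(Y) == 0, 4] <- 1L
  list(X = X, Y = Y)
}

test_that("labelset ensemble with one full set is plain label powerset", {
  toy <- toy_multilabel()
  fit <- rakel_fit(toy$X, toy$Y, k_r = 4, m = 1, seed = 1)
  expect_length(fit$members, 1)
  expect_equal(fit$members[[1]]$labels, 1:4)
  pred <- rakel_predict(fit, toy$X)
  # single voter: scores are 0/1 and equal the bipartition
  expect_true(all(pred$scores %in% c(0, 1)))
  expect_equal(unname(pred$scores), unname(pred$bipartition * 1))
})

test_that("vote fractions equal a hand tally of member predictions", {
  toy <- toy_multilabel()
  fit <- rakel_fit(toy$X, toy$Y, k_r = 3, m = 4, seed = 7)
  pred <- rakel_predict(fit, toy$X)
  votes <- matrix(0, nrow(toy$X), 4)
  appearances <- numeric(4)
  for (mem in fit$members) {
    appearances[mem$labels] <- appearances[mem$labels] + 1
    cls <- fit$base_learner$predict(mem$fit, toy$X, type = "class")
    bits <- matrix(as.numeric(do.call(rbind, strsplit(cls, ""))),
                   nrow = nrow(toy$X))
    votes[, mem$labels] <- votes[, mem$labels] + bits
  }
  expect_equal(unname(pred$scores), votes / pmax(appearances, 1),
               tolerance = 1e-12)
})

test_that("labelset draw rules are enforced", {
  toy <- toy_multilabel()
  expect_error(rakel_fit(toy$X, toy$Y, k_r = 3, m = 5), "distinct labelsets")
  # with Q = 4, k_r = 1, m = 2: two labels never covered
  expect_warning(fit <- rakel_fit(toy$X, toy$Y, k_r = 1, m = 2, seed = 3),
                 "score 0")
  pred <- rakel_predict(fit, toy$X[1:5, ])
  expect_true(all(pred$scores[, fit$uncovered] == 0))
})

test_that("chain of one label equals a single binary classifier", {
  toy <- toy_multilabel()
  Y1 <- toy$Y[, 1, drop = FALSE]
  fit <- cc_fit(toy$X, Y1)
  learner <- make_logistic_learner()
  ref <- learner$fit(toy$X, Y1[, 1])
  expect_equal(cc_predict(fit, toy$X)$scores[, 1],
               learner$predict(ref, toy$X, type = "prob"),
               tolerance = 1e-8)
})

test_that("a deterministic copy label is predicted perfectly via the chain", {
  toy <- toy_multilabel(n = 80)
  fit <- cc_fit(toy$X, toy$Y)
  pred <- cc_predict(fit, toy$X)
  # label 3 copies label 1, which precedes it in the chain
  expect_equal(pred$bipartition[, 3], toy$Y[, 3])
})

test_that("constant label columns yield constant predictions with warning", {
  toy <- toy_multilabel()
  Yc <- toy$Y
  Yc[, 2] <- 1L
  expect_warning(fit <- cc_fit(toy$X, Yc), "constant")
  pred <- cc_predict(fit, toy$X)
  expect_true(all(pred$bipartition[, 2] == 1))
})

test_that("random chain order is a seeded permutation", {
  toy <- toy_multilabel()
  f1 <- cc_fit(toy$X, toy$Y, chain_order = "random", seed = 5)
  f2 <- cc_fit(toy$X, toy$Y, chain_order = "random", seed = 5)
  expect_identical(f1$chain_order, f2$chain_order)
  expect_setequal(f1$chain_order, 1:4)
})

test_that("rakel and cc fits are reproducible and consistent with scores", {
  toy <- toy_multilabel()
  r1 <- rakel_fit(toy$X, toy$Y, k_r = 2, m = 4, seed = 11)
  r2 <- rakel_fit(toy$X, toy$Y, k_r = 2, m = 4, seed = 11)
  expect_equal(r1[setdiff(names(r1), "base_learner")],
               r2[setdiff(names(r2), "base_learner")])
  pred <- rakel_predict(r1, toy$X)
  expect_identical(pred$bipartition, (pred$scores > 0.5) * 1L)
  cpred <- cc_predict(cc_fit(toy$X, toy$Y), toy$X)
  expect_identical(unname(cpred$bipartition),
                   unname((cpred$scores > 0.5) * 1))
})
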