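test_that("label similarity is the cosine of term-frequency vectors", {
  expect_equal(label_similarity("placenta previa", "placenta previa"), 1.0)
  expect_equal(label_similarity("anemia", "placenta previa"), 0.0)
  # {placenta, previa} vs {state, placenta, previa}: 2 / (sqrt(2) sqrt(3))
  expect_equal(label_similarity("placenta previa", "state placenta previa"),
               2 / (sqrt(2) * sqrt(3)), tolerance = 1e-12)
  expect_warning(s <- label_similarity("", "anemia"), "zero")
  expect_equal(s, 0)
})

test_that("label similarity is symmetric and bounded on random labels", {
  set.seed(31)
  words <- c("alpha", "beta", "gamma", "delta", "epsilon")
  for (i in 1:25) {
    a <- paste(sample(words, sample(1:4, 1), replace = TRUE), collapse = " ")
    b <- paste(sample(words, sample(1:4, 1), replace = TRUE), collapse = " ")
    s1 <- label_similarity(a, b)
    s2 <- label_similarity(b, a)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_gte(s1, 0)
    expect_lte(s1, 1 + 1e-12)
  }
})

test_that("label merging clusters by single linkage with frequency canon", {
  # disjoint labels at threshold 1.0: identity merge map
  sp <- merge_labels(c("anemia", "edema", "edema"), threshold = 1.0)
  expect_equal(sort(sp$labels), c("anemia", "edema"))
  expect_equal(unname(sp$merge_map[c("anemia", "edema")]),
               c("anemia", "edema"))

  # cosine 0.8165 pair merges at threshold 0.8 under the more frequent form
  raw <- c(rep("placenta previa", 3), "state placenta previa", "anemia")
  sp2 <- merge_labels(raw, threshold = 0.8)
  expect_equal(unname(sp2$merge_map["state placenta previa"]),
               "placenta previa")
  expect_equal(unname(sp2$freq["placenta previa"]), 4L)

  # single-linkage chain: A~B and B~C merge all three though A~C is distant
  chain <- c("a b", "b c", "c d")
  sims <- c(label_similarity("a b", "b c"), label_similarity("b c", "c d"),
            label_similarity("a b", "c d"))
  expect_equal(sims, c(0.5, 0.5, 0), tolerance = 1e-9)
  sp3 <- merge_labels(chain, threshold = 0.45)
  expect_length(sp3$labels, 1)
})

test_that("label merging is idempotent", {
  raw <- c(rep("placenta previa", 3), "state placenta previa",
           "anemia", "gestational anemia")
  sp <- merge_labels(raw, threshold = 0.7)
  canon <- unname(sp$merge_map[raw])
  sp2 <- merge_labels(canon, threshold = 0.7)
  expect_equal(sp2$labels, sp$labels)
  expect_equal(sp2$freq, sp$freq)
})

test_that("frequency filtering thresholds labels and composes", {
  fix <- small_corpus_fixture(n_records = 120, n_labels = 15, seed = 13)
  freqs <- fix$space$freq

  r1 <- filter_labels_by_frequency(fix$Y, fix$space, 1)
  expect_identical(r1$matrix, fix$Y[rowSums(fix$Y) > 0, , drop = FALSE])
  expect_equal(r1$space$labels, fix$space$labels)

  r2 <- filter_labels_by_frequency(fix$Y, fix$space, 2)
  expect_true(all(fix$space$freq[r2$space$labels] >= 2))

  # filtering at 2 then 11 equals filtering at 11 directly
  r2_11 <- filter_labels_by_frequency(r2$matrix, r2$space, 11)
  r11 <- filter_labels_by_frequency(fix$Y, fix$space, 11)
  expect_equal(r2_11$space$labels, r11$space$labels)
  expect_equal(unname(r2_11$matrix), unname(r11$matrix))

  expect_error(filter_labels_by_frequency(fix$Y, fix$space,
                                          max(freqs) + 1L), "every label")
})

test_that("label matrix rows stay within the 1..8 cardinality band", {
  fix <- small_corpus_fixture(n_records = 150, n_labels = 10, seed = 17)
  rs <- rowSums(fix$Y)
  expect_gte(min(rs), 1)
  expect_lte(max(rs), 8)
})

test_that("label space serialization round-trips", {
  fix <- small_corpus_fixture(n_records = 60, n_labels = 8, seed = 19)
  base <- withr::local_tempfile()
  write_label_space(fix$space, base)
  sp <- read_label_space(base)
  expect_equal(sp$labels, fix$space$labels)
  expect_equal(sp$freq, fix$space$freq)
  expect_equal(sp$merge_map, fix$space$merge_map)
})
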