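# Shared fixtures, built in code at test time.

# small strong-signal corpus + standardized label space + label matrix
small_corpus_fixture <- function(n_records = 200, n_labels = 12,
                                 vocab_size = 300, seed = 7) {
  cfg <- synthetic_config(n_records = n_records, n_labels = n_labels,
                          vocab_size = vocab_size, seed = seed)
  gen <- generate_corpus(cfg)
  raw <- unlist(lapply(gen$corpus, `[[`, "diagnoses"), use.names = FALSE)
  space <- merge_labels(raw)
  Y <- build_label_matrix(gen$corpus, space)
  list(config = cfg, corpus = gen$corpus, truth = gen$truth,
       space = space, Y = Y)
}

# hand-buildable record
make_record <- function(id, chief = character(0), phys = character(0),
                        obst = character(0), aux = character(0),
                        diagnoses = character(0), ...) {
  c(list(id = id, chief_complaints = chief, physical_exam = phys,
         obstetric_exam = obst, auxiliary_exam = aux,
         diagnoses = diagnoses), list(...))
}

# independent brute-force implementations of the five measures, written as
# direct set/pair enumeration (no shared code with the package internals)
oracle_rank <- function(s) {
  ord <- order(-s, seq_along(s))
  r <- integer(length(s)); r[ord] <- seq_along(s); r
}

oracle_metrics <- function(scores, bipartition, truth) {
  p <- nrow(truth); Q <- ncol(truth)
  hl <- 0; oe <- 0; cv <- 0; rl <- 0; ap <- 0
  n_oe <- 0; n_rl <- 0
  for (i in seq_len(p)) {
    hl <- hl + length(which(bipartition[i, ] != truth[i, ])) / Q
    Yi <- which(truth[i, ] == 1)
    Ni <- which(truth[i, ] == 0)
    if (length(Yi) > 0) {
      n_oe <- n_oe + 1
      r <- oracle_rank(scores[i, ])
      oe <- oe + as.numeric(!(which(r == 1) %in% Yi))
      cv <- cv + max(r[Yi]) - 1
      prec <- 0
      for (y in Yi) prec <- prec + sum(r[Yi] <= r[y]) / r[y]
      ap <- ap + prec / length(Yi)
      if (length(Ni) > 0) {
        n_rl <- n_rl + 1
        bad <- 0
        for (y1 in Yi) for (y2 in Ni)
          if (scores[i, y1] <= scores[i, y2]) bad <- bad + 1
        rl <- rl + bad / (length(Yi) * length(Ni))
      }
    }
  }
  c(hamming_loss = hl / p, one_error = oe / n_oe, coverage = cv / n_oe,
    ranking_loss = rl / n_rl, average_precision = ap / n_oe)
}

# random multilabel evaluation instance with non-degenerate rows
random_eval_case <- function(p, Q) {
  truth <- matrix(0L, p, Q)
  for (i in seq_len(p)) {
    k <- sample(seq_len(Q - 1), 1)
    truth[i, sample(Q, k)] <- 1L
  }
  scores <- matrix(stats::rnorm(p * Q), p, Q)
  bipartition <- matrix(stats::rbinom(p * Q, 1, 0.5), p, Q)
  list(scores = scores, bipartition = bipartition, truth = truth)
}

# independent brute-force posterior for a query: direct Bayesian computation
# from counting over the training set, no shared code with mlknn_fit
brute_mlknn_score <- function(X, Y, k, s, x) {
  p <- nrow(X); Q <- ncol(Y)
  # neighbor counts of each training point (self excluded)
  near <- function(ref, pool_idx) {
    d <- sqrt(colSums((t(X[pool_idx, , drop = FALSE]) - ref)^2))
    pool_idx[order(d, pool_idx)][seq_len(k)]
  }
  out <- numeric(Q)
  for (j in seq_len(Q)) {
    prior <- (s + sum(Y[, j])) / (2 * s + p)
    # neighbor-count histograms per hypothesis
    c1 <- integer(k + 1); c0 <- integer(k + 1)
    for (i in seq_len(p)) {
      nb <- near(X[i, ], setdiff(seq_len(p), i))
      cnt <- sum(Y[nb, j])
      if (Y[i, j] == 1) c1[cnt + 1] <- c1[cnt + 1] + 1L
      else c0[cnt + 1] <- c0[cnt + 1] + 1L
    }
    nb_q <- near(x, seq_len(p))
    cq <- sum(Y[nb_q, j])
    pe_h <- (s + c1[cq + 1]) / (s * (k + 1) + sum(c1))
    pe_nh <- (s + c0[cq + 1]) / (s * (k + 1) + sum(c0))
    out[j] <- prior * pe_h / (prior * pe_h + (1 - prior) * pe_nh)
  }
  out
}

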