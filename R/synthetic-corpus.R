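#' @useDynLib mldx, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

SECTION_KEYS <- c("chief_complaints", "physical_exam",
                  "obstetric_exam", "auxiliary_exam")

#' Configuration for the synthetic sectioned-record generator
#'
#' Describes a synthetic corpus of first-course clinical records: each record
#' carries four token-sequence sections and a set of 1--8 diagnosis labels.
#' Labels carry signal through topics: every label has a dominant topic in a
#' planted topic-word distribution, and a record's tokens are emitted from
#' the mixture of its labels' topics, so diagnoses are statistically
#' predictable from section text.
#'
#' @param n_records number of records to generate.
#' @param n_labels size Q of the diagnosis label space.
#' @param n_topics_true number of planted topics; defaults to `n_labels`
#'   (one dominant topic per label, the strong-signal regime).
#' @param vocab_size number of distinct token types.
#' @param section_lengths named numeric vector of mean token counts for the
#'   four sections (`chief_complaints`, `physical_exam`, `obstetric_exam`,
#'   `auxiliary_exam`); section lengths are Poisson with these means.
#' @param cardinality_dist probability vector over label counts 1..8; the
#'   default is a truncated geometric calibrated to mean 2.67.
#' @param label_skew exponent of the power-law (Zipf) label frequency
#'   weights, `weight(rank) = rank^-label_skew`.
#' @param noise_floor total probability mass of the uniform noise component
#'   in each label's topic-affinity row.
#' @param dirichlet_alpha per-topic pseudo-count smoothing the record-level
#'   topic mixture.
#' @param dirichlet_beta symmetric Dirichlet concentration of the planted
#'   topic-word rows; small values give well-separated (sparse) topics.
#' @param seed integer seed; the same configuration generates a
#'   byte-identical corpus.
#'
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 2000,
                             n_labels = 60,
                             n_topics_true = n_labels,
                             vocab_size = 2000,
                             section_lengths = c(chief_complaints = 15,
                                                 physical_exam = 25,
                                                 obstetric_exam = 20,
                                                 auxiliary_exam = 15),
                             cardinality_dist =
                               cardinality_from_mean(2.67, min(8L, n_labels)),
                             label_skew = 1.5,
                             noise_floor = 0.05,
                             dirichlet_alpha = 0.005,
                             dirichlet_beta = 0.1,
                             seed = 1L) {
  stopifnot(n_records >= 0, n_labels >= 1, n_topics_true >= 1,
            vocab_size >= 1, dirichlet_alpha > 0, dirichlet_beta > 0,
            noise_floor >= 0, noise_floor < 1)
  if (n_topics_true > vocab_size)
    stop("n_topics_true must not exceed vocab_size")
  if (!all(SECTION_KEYS %in% names(section_lengths)))
    stop("section_lengths must name all four sections")
  if (length(cardinality_dist) > 8L || any(cardinality_dist < 0))
    stop("cardinality_dist must be a probability vector with support in 1..8")
  if (abs(sum(cardinality_dist) - 1) > 1e-8)
    stop("cardinality_dist must sum to 1")
  if (max(which(cardinality_dist > 0)) > n_labels)
    stop("label cardinality support exceeds n_labels")
  structure(list(n_records = as.integer(n_records),
                 n_labels = as.integer(n_labels),
                 n_topics_true = as.integer(n_topics_true),
                 vocab_size = as.integer(vocab_size),
                 section_lengths = section_lengths[SECTION_KEYS],
                 cardinality_dist = cardinality_dist,
                 label_skew = label_skew,
                 noise_floor = noise_floor,
                 dirichlet_alpha = dirichlet_alpha,
                 dirichlet_beta = dirichlet_beta,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Truncated-geometric label-count distribution with a given mean
#'
#' Solves for the ratio r of a geometric distribution truncated to
#' 1..`max_card` whose mean equals `target_mean`. Used as the default
#' per-record label-count (cardinality) distribution, calibrated to the
#' observed mean of 2.67 labels per record with minimum 1 and maximum 8.
#'
#' @param target_mean desired mean label count, in (1, `max_card`).
#' @param max_card largest label count in the support (default 8).
#' @return probability vector of length `max_card` over counts
#'   1..`max_card`.
#' @export
cardinality_from_mean <- function(target_mean = 2.67, max_card = 8L) {
  stopifnot(max_card >= 2, target_mean > 1, target_mean < max_card)
  ks <- seq_len(max_card)
  mean_at <- function(r) {
    w <- r^(ks - 1)
    sum(ks * w) / sum(w)
  }
  # r < 1 gives a decreasing count distribution; r > 1 (allowed when the
  # target mean exceeds the midpoint) an increasing one
  r <- stats::uniroot(function(r) mean_at(r) - target_mean,
                      interval = c(1e-9, 1e6), tol = 1e-12)$root
  w <- r^(ks - 1)
  w / sum(w)
}

#' Generate a synthetic corpus of sectioned records
#'
#' Generative process: (1) label frequency weights follow a power law with
#' exponent `label_skew`; (2) each record draws its label count from
#' `cardinality_dist` and samples that many distinct labels proportional to
#' the weights; (3) the record's topic mixture is the normalized sum of its
#' labels' topic-affinity rows plus `dirichlet_alpha` pseudo-counts; (4) each
#' section emits Poisson-many tokens, each by drawing a topic from the
#' mixture and then a token type from the planted topic-word row (the
#' standard latent-Dirichlet-allocation emission).
#'
#' @param config a [synthetic_config()].
#' @return list with `corpus` (list of records; each has `id`, the four
#'   section token vectors, and `diagnoses`) and `truth` (planted
#'   `topic_word_true`, `label_topic_affinity`, `label_weights`,
#'   `per_record_labels`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_topics_true
  Q <- config$n_labels
  W <- config$vocab_size

  label_names <- sprintf("dx%03d", seq_len(Q))
  vocab <- sprintf("w%04d", seq_len(W))

  # planted topics: rows of a symmetric Dirichlet
  topic_word_true <- matrix(stats::rgamma(K * W, shape = config$dirichlet_beta),
                            nrow = K)
  topic_word_true <- topic_word_true / rowSums(topic_word_true)
  rownames(topic_word_true) <- sprintf("topic%03d", seq_len(K))
  colnames(topic_word_true) <- vocab

  # each label leans on one dominant topic plus a uniform noise floor
  dominant <- ((seq_len(Q) - 1L) %% K) + 1L
  affinity <- matrix(config$noise_floor / K, nrow = Q, ncol = K)
  affinity[cbind(seq_len(Q), dominant)] <-
    affinity[cbind(seq_len(Q), dominant)] + (1 - config$noise_floor)
  rownames(affinity) <- label_names

  label_weights <- seq_len(Q)^(-config$label_skew)
  label_weights <- label_weights / sum(label_weights)
  names(label_weights) <- label_names

  card_support <- seq_along(config$cardinality_dist)
  per_record_labels <- vector("list", config$n_records)
  corpus <- vector("list", config$n_records)

  for (i in seq_len(config$n_records)) {
    card <- sample(card_support, 1L, prob = config$cardinality_dist)
    labs <- sample.int(Q, card, replace = FALSE, prob = label_weights)
    mix <- colSums(affinity[labs, , drop = FALSE]) + config$dirichlet_alpha
    mix <- mix / sum(mix)
    sections <- stats::setNames(vector("list", 4L), SECTION_KEYS)
    for (s in SECTION_KEYS) {
      len <- stats::rpois(1L, config$section_lengths[[s]])
      if (len == 0L) {
        sections[[s]] <- character(0)
      } else {
        z <- sample.int(K, len, replace = TRUE, prob = mix)
        w <- integer(len)
        for (k in sort(unique(z))) {
          idx <- which(z == k)
          w[idx] <- sample.int(W, length(idx), replace = TRUE,
                               prob = topic_word_true[k, ])
        }
        sections[[s]] <- vocab[w]
      }
    }
    per_record_labels[[i]] <- sort(label_names[labs])
    corpus[[i]] <- c(list(id = sprintf("rec%05d", i)),
                     sections,
                     list(diagnoses = per_record_labels[[i]]))
  }

  truth <- list(topic_word_true = topic_word_true,
                label_topic_affinity = affinity,
                label_weights = label_weights,
                per_record_labels = per_record_labels)
  list(corpus = corpus, truth = truth)
}

#' Write a corpus as JSON-lines
#'
#' One JSON object per line with fields `id`, the four section token arrays,
#' and `diagnoses`.
#'
#' @param corpus list of records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    stopifnot(all(SECTION_KEYS %in% names(rec)))
    obj <- list(id = jsonlite::unbox(as.character(rec$id)))
    for (s in SECTION_KEYS) obj[[s]] <- as.character(rec[[s]])
    obj$diagnoses <- as.character(rec$diagnoses)
    as.character(jsonlite::toJSON(obj))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path file written by [write_corpus()].
#' @return list of records.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("malformed corpus line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    missing <- setdiff(c("id", SECTION_KEYS, "diagnoses"), names(obj))
    if (length(missing))
      stop(sprintf("corpus line %d is missing field(s): %s",
                   i, paste(missing, collapse = ", ")), call. = FALSE)
    rec <- list(id = as.character(obj$id))
    for (s in SECTION_KEYS) rec[[s]] <- as.character(unlist(obj[[s]]))
    rec$diagnoses <- as.character(unlist(obj$diagnoses))
    rec
  })
}

#' Concatenate a record's four sections into one token sequence
#' @param record a corpus record.
#' @return character vector of tokens.
#' @export
record_tokens <- function(record) {
  unlist(lapply(SECTION_KEYS, function(s) record[[s]]), use.names = FALSE)
}

#' Map a corpus to integer token-id documents over a shared vocabulary
#'
#' Sections are concatenated into one document per record. When `vocab` is
#' supplied, tokens outside it are dropped (out-of-vocabulary).
#'
#' @param corpus list of records.
#' @param vocab optional character vector fixing the vocabulary.
#' @return list with `docs` (list of integer vectors, 1-based ids) and
#'   `vocab`.
#' @export
corpus_documents <- function(corpus, vocab = NULL) {
  toks <- lapply(corpus, record_tokens)
  if (is.null(vocab))
    vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  docs <- lapply(toks, function(tt) {
    ids <- match(tt, vocab)
    ids[!is.na(ids)]
  })
  list(docs = docs, vocab = vocab)
}
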