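#' Configuration of one feature-extractor / classifier pipeline
#'
#' Bundles the choices needed to run one classifier on one feature type;
#' consumed by [cross_validate()] and the experiment runners.
#'
#' @param feature `"lda"` (document-topic proportions) or `"word_vector"`
#'   (mean-pooled skip-gram document vectors).
#' @param classifier one of `"bpmll"`, `"mlknn"`, `"rakel"`, `"cc"`.
#' @param K topic count for the topic-model feature.
#' @param lda_alpha document-topic smoothing used when fitting the feature
#'   topic model; `NULL` keeps the [fit_lda()] default `50 / K`.
#' @param lda_chains number of independently seeded Gibbs chains; the
#'   feature blocks of all chains are concatenated (topics are not aligned
#'   across chains, so blocks are joined, never averaged), which damps the
#'   topic-recovery noise of any single chain.
#' @param lda_iter,foldin_iter Gibbs sweeps for fitting and for folding in
#'   held-out documents.
#' @param T_dim embedding dimension for the word-vector feature.
#' @param window,sg_epochs,n_negative skip-gram context half-width, epochs,
#'   and negative samples per pair.
#' @param sg_lr skip-gram initial learning rate (linear decay); 0.05 rather
#'   than the classic 0.025 suits short training runs on small corpora.
#' @param feature_map `"identity"`, or `"sqrt"` for the Hellinger embedding
#'   of probability features (the element-wise square root, under which
#'   Euclidean distance approximates Hellinger distance between topic
#'   proportions; useful for distance-based classifiers).
#' @param classifier_params named list of extra arguments for the
#'   classifier's fit function.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(feature = c("lda", "word_vector"),
                            classifier = c("mlknn", "bpmll", "rakel", "cc"),
                            K = 60L, lda_alpha = NULL, lda_chains = 1L,
                            lda_iter = 200L, foldin_iter = 50L,
                            T_dim = 100L, window = 5L, sg_epochs = 5L,
                            n_negative = 5L, sg_lr = 0.05,
                            feature_map = c("identity", "sqrt"),
                            classifier_params = list()) {
  structure(list(feature = match.arg(feature),
                 classifier = match.arg(classifier),
                 K = as.integer(K), lda_alpha = lda_alpha,
                 lda_chains = as.integer(lda_chains),
                 lda_iter = as.integer(lda_iter),
                 foldin_iter = as.integer(foldin_iter),
                 T_dim = as.integer(T_dim), window = as.integer(window),
                 sg_epochs = as.integer(sg_epochs),
                 n_negative = as.integer(n_negative), sg_lr = sg_lr,
                 feature_map = match.arg(feature_map),
                 classifier_params = classifier_params),
            class = "pipeline_config")
}

feature_fields <- function(cfg) {
  cfg[c("feature", "K", "lda_alpha", "lda_chains", "lda_iter",
        "foldin_iter", "T_dim", "window", "sg_epochs", "n_negative",
        "sg_lr", "feature_map")]
}

# fit the configured feature extractor on training records only and return
# train/test feature matrices (held-out docs folded in, never fitted on)
extract_features <- function(config, corpus_train, corpus_test, seed) {
  if (config$feature == "lda") {
    dd <- corpus_documents(corpus_train)
    te <- corpus_documents(corpus_test, vocab = dd$vocab)
    alpha <- if (is.null(config$lda_alpha)) 50 / config$K else config$lda_alpha
    chains <- lapply(seq_len(max(1L, config$lda_chains)), function(ch) {
      chain_seed <- seed + 57L * (ch - 1L)
      m <- fit_lda(dd$docs, K = config$K, vocab = dd$vocab, alpha = alpha,
                   n_iter = config$lda_iter, seed = chain_seed)
      list(model = m,
           train = doc_topic_features(m),
           test = infer_doc_topics(m, te$docs,
                                   n_iter = config$foldin_iter,
                                   seed = chain_seed + 1L))
    })
    model <- chains[[1]]$model
    Xtr <- do.call(cbind, lapply(chains, `[[`, "train"))
    Xte <- do.call(cbind, lapply(chains, `[[`, "test"))
    colnames(Xtr) <- colnames(Xte) <-
      sprintf("topic_%d", seq_len(ncol(Xtr)) - 1L)
  } else {
    dd <- corpus_documents(corpus_train)
    model <- fit_skipgram(dd$docs, dd$vocab, dim = config$T_dim,
                          window = config$window, epochs = config$sg_epochs,
                          learning_rate = config$sg_lr,
                          n_negative = config$n_negative, seed = seed)
    Xtr <- doc_vector_features(model, corpus_train)
    Xte <- suppressWarnings(doc_vector_features(model, corpus_test))
  }
  if (identical(config$feature_map, "sqrt")) {
    if (config$feature != "lda")
      stop("the sqrt (Hellinger) feature map applies to probability features only")
    Xtr <- sqrt(Xtr)
    Xte <- sqrt(Xte)
  }
  list(train = Xtr, test = Xte, model = model)
}

# dispatch to the configured classifier's fit / predict pair
fit_multilabel <- function(config, X, Y, seed) {
  args <- config$classifier_params
  switch(config$classifier,
         bpmll = do.call(bpmll_fit, c(list(X = X, Y = Y, seed = seed), args)),
         mlknn = do.call(mlknn_fit, c(list(X = X, Y = Y), args)),
         rakel = do.call(rakel_fit, c(list(X = X, Y = Y, seed = seed), args)),
         cc = do.call(cc_fit, c(list(X = X, Y = Y, seed = seed), args)))
}

predict_multilabel <- function(config, model, X) {
  switch(config$classifier,
         bpmll = bpmll_predict(model, X),
         mlknn = mlknn_predict(model, X),
         rakel = rakel_predict(model, X),
         cc = cc_predict(model, X))
}

#' Cross-validated evaluation of one pipeline
#'
#' Random instance partition into `n_folds` folds (seeded). For each fold
#' the feature extractor and the classifier are fitted on the training
#' folds only — held-out records obtain topic features by fold-in sampling
#' and embedding features through the frozen vector tables, so no test
#' token influences any fitted parameter — and the five multilabel measures
#' are computed on the held-out fold. Training rows left without a positive
#' label are dropped from the fit.
#'
#' @param corpus list of records.
#' @param Y binary label matrix aligned with `corpus` rows.
#' @param config a [pipeline_config()], or a list of them sharing identical
#'   feature settings (the feature extractor is then fitted once per fold
#'   and reused by every classifier).
#' @param n_folds number of folds (>= 2); default 10.
#' @param seed integer seed driving the fold split and every fit.
#' @return a `metric_report` (per-fold values plus mean and sample standard
#'   deviation of the five measures), or a list of them named by classifier
#'   when `config` is a list.
#' @export
cross_validate <- function(corpus, Y, config, n_folds = 10L, seed = 1L) {
  single <- inherits(config, "pipeline_config")
  configs <- if (single) list(config) else config
  stopifnot(all(vapply(configs, inherits, logical(1), "pipeline_config")))
  ff <- lapply(configs, feature_fields)
  if (!all(vapply(ff, identical, logical(1), ff[[1]])))
    stop("all pipeline configs must share identical feature settings")

  p <- length(corpus)
  stopifnot(nrow(Y) == p, n_folds >= 2, n_folds <= p)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(n_folds), p))

  metric_names <- c("hamming_loss", "one_error", "coverage",
                    "ranking_loss", "average_precision")
  per_fold <- lapply(configs, function(cfg)
    matrix(NA_real_, nrow = n_folds, ncol = 5,
           dimnames = list(NULL, metric_names)))
  for (f in seq_len(n_folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    tr <- tr[rowSums(Y[tr, , drop = FALSE]) > 0]
    fold_seed <- seed + 1000L * f
    feats <- extract_features(configs[[1]], corpus[tr], corpus[te], fold_seed)
    for (ci in seq_along(configs)) {
      model <- fit_multilabel(configs[[ci]], feats$train,
                              Y[tr, , drop = FALSE], fold_seed)
      pred <- predict_multilabel(configs[[ci]], model, feats$test)
      per_fold[[ci]][f, ] <- suppressWarnings(
        evaluate_multilabel(pred$scores, pred$bipartition,
                            Y[te, , drop = FALSE]))
    }
  }
  reports <- lapply(seq_along(configs), function(ci)
    structure(list(per_fold = per_fold[[ci]],
                   mean = colMeans(per_fold[[ci]]),
                   sd = apply(per_fold[[ci]], 2, stats::sd),
                   n_folds = as.integer(n_folds),
                   config = configs[[ci]],
                   seed = as.integer(seed)),
              class = "metric_report"))
  if (single) return(reports[[1]])
  stats::setNames(reports, vapply(configs, `[[`, character(1), "classifier"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s on %s features, %d-fold cross-validation (seed %d)\n",
              x$config$classifier, x$config$feature, x$n_folds, x$seed))
  for (m in names(x$mean))
    cat(sprintf("  %-18s %s\n", m, format_mean_sd(x$mean[m], x$sd[m])))
  invisible(x)
}

format_mean_sd <- function(m, s) sprintf("%.4f ± %.4f", m, s)
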