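#' Configuration of a comparative experiment run
#'
#' Mirrors the study's three experiment axes on a synthetic corpus: the
#' label-frequency floor (label-set size), the topic count K of the
#' topic-model feature, and the dimension T of the word-vector feature.
#'
#' @param synthetic a [synthetic_config()] describing the corpus; ignored
#'   when `corpus` and `Y`/`space` are supplied directly to the runners.
#' @param min_keep_freq integer vector of label-frequency floors (1 keeps
#'   all labels; 2 drops singletons; 11 keeps frequency >= 11).
#' @param features subset of `c("lda", "word_vector")`.
#' @param classifiers subset of `c("mlknn", "bpmll", "rakel", "cc")`.
#' @param K_list topic counts for the topic sweep.
#' @param T_list embedding dimensions for the dimension sweep.
#' @param n_folds cross-validation folds.
#' @param seed master seed; every stage derives its seed from it.
#' @param output_dir directory for report files.
#' @param pipeline_defaults named list of overrides passed to
#'   [pipeline_config()] (e.g. smaller `lda_iter` for quick runs).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(synthetic = synthetic_config(),
                              min_keep_freq = c(1L, 2L, 11L),
                              features = c("lda", "word_vector"),
                              classifiers = c("mlknn", "bpmll", "rakel", "cc"),
                              K_list = c(40L, 60L, 80L),
                              T_list = c(10L, 50L, 100L),
                              n_folds = 5L,
                              seed = 1L,
                              output_dir = "results",
                              pipeline_defaults = list()) {
  stopifnot(length(features) >= 1, length(classifiers) >= 1)
  structure(list(synthetic = synthetic,
                 min_keep_freq = as.integer(min_keep_freq),
                 features = match.arg(features, c("lda", "word_vector"),
                                      several.ok = TRUE),
                 classifiers = match.arg(classifiers,
                                         c("mlknn", "bpmll", "rakel", "cc"),
                                         several.ok = TRUE),
                 K_list = as.integer(K_list), T_list = as.integer(T_list),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 output_dir = output_dir,
                 pipeline_defaults = pipeline_defaults),
            class = "experiment_config")
}

# materialize the corpus + label matrix once per experiment
experiment_data <- function(config) {
  gen <- generate_corpus(config$synthetic)
  raw <- unlist(lapply(gen$corpus, `[[`, "diagnoses"), use.names = FALSE)
  space <- merge_labels(raw)
  Y <- build_label_matrix(gen$corpus, space)
  list(corpus = gen$corpus, truth = gen$truth, space = space, Y = Y)
}

make_pipeline <- function(config, feature, classifier, ...) {
  defaults <- config$pipeline_defaults
  # classifier_params may be one list for all classifiers, or a named list
  # of per-classifier parameter lists
  cp <- defaults$classifier_params
  if (!is.null(cp) && any(names(cp) %in%
                          c("mlknn", "bpmll", "rakel", "cc"))) {
    defaults$classifier_params <- if (is.null(cp[[classifier]]))
      list() else cp[[classifier]]
  }
  if (identical(feature, "word_vector"))
    defaults$feature_map <- NULL   # Hellinger map applies to topic features
  do.call(pipeline_config,
          utils::modifyList(c(list(feature = feature, classifier = classifier),
                              defaults),
                            list(...)))
}

report_header <- function(config, extra = character(0)) {
  c(sprintf("# seed: %d", config$seed),
    sprintf("# n_folds: %d", config$n_folds),
    extra)
}

#' Compare classifiers across label-set sizes
#'
#' For each label-frequency floor, reduces the label space, drops records
#' left without labels, cross-validates every classifier x feature
#' combination, and writes one tab-separated table per floor with all five
#' measures as "mean ± sd"; the best value in each metric column is flagged
#' with `*`. Reports are byte-identical across reruns with the same seed.
#'
#' @param config an [experiment_config()].
#' @return named list of per-floor results (data frame plus file path),
#'   invisibly.
#' @export
run_label_set_experiment <- function(config) {
  dat <- experiment_data(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (floor in config$min_keep_freq) {
    t0 <- proc.time()[3]
    red <- filter_labels_by_frequency(dat$Y, dat$space, floor)
    corpus_f <- if (length(red$dropped_instances))
      dat$corpus[-red$dropped_instances] else dat$corpus
    rows <- list()
    for (feat in config$features) {
      cfgs <- lapply(config$classifiers, function(cls)
        make_pipeline(config, feat, cls))
      reps <- cross_validate(corpus_f, red$matrix, cfgs,
                             n_folds = config$n_folds, seed = config$seed)
      for (cls in names(reps)) {
        rep <- reps[[cls]]
        rows[[length(rows) + 1L]] <-
          data.frame(classifier = cls, feature = feat,
                     t(rep$mean), t(stats::setNames(rep$sd,
                                                    paste0(names(rep$sd), "_sd"))))
      }
    }
    tab <- do.call(rbind, rows)
    path <- file.path(config$output_dir,
                      sprintf("label_set_floor%02d.tsv", floor))
    write_experiment_table(tab, path,
                           report_header(config,
                                         sprintf("# min_keep_freq: %d (Q = %d)",
                                                 floor, ncol(red$matrix))))
    message(sprintf("label-set floor %d (Q = %d): %.1fs",
                    floor, ncol(red$matrix), proc.time()[3] - t0))
    out[[as.character(floor)]] <- list(table = tab, path = path,
                                       Q = ncol(red$matrix))
  }
  invisible(out)
}

# mean ± sd table with per-column best flags, stable column order
write_experiment_table <- function(tab, path, header) {
  metrics <- c("hamming_loss", "one_error", "coverage", "ranking_loss",
               "average_precision")
  better_high <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  disp <- tab[, c("classifier", "feature")]
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    vals <- tab[[m]]
    best <- if (better_high[i]) max(vals) else min(vals)
    disp[[m]] <- sprintf("%s%s",
                         mapply(format_mean_sd, vals, tab[[paste0(m, "_sd")]]),
                         ifelse(vals == best, " *", ""))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(disp, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sweep_axis <- function(config, axis_name, values, feature, make_cfg) {
  dat <- experiment_data(config)
  red <- filter_labels_by_frequency(dat$Y, dat$space,
                                    max(config$min_keep_freq))
  corpus_f <- if (length(red$dropped_instances))
    dat$corpus[-red$dropped_instances] else dat$corpus
  rows <- list()
  for (v in values) {
    t0 <- proc.time()[3]
    cfgs <- lapply(config$classifiers, function(cls) make_cfg(v, cls))
    reps <- cross_validate(corpus_f, red$matrix, cfgs,
                           n_folds = config$n_folds, seed = config$seed)
    for (cls in names(reps)) {
      rep <- reps[[cls]]
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(classifier = cls, axis = v),
              data.frame(t(rep$mean)),
              data.frame(t(stats::setNames(rep$sd,
                                           paste0(names(rep$sd), "_sd")))))
      message(sprintf("%s = %d, %s: AP %.4f", axis_name, v, cls,
                      rep$mean["average_precision"]))
    }
    message(sprintf("%s = %d: %.1fs", axis_name, v, proc.time()[3] - t0))
  }
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "axis"] <- axis_name
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$output_dir, sprintf("sweep_%s.tsv", axis_name))
  con <- file(path, "w")
  writeLines(report_header(config,
                           sprintf("# feature: %s, Q floor: %d", feature,
                                   max(config$min_keep_freq))), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(list(table = tab, path = path))
}

#' Sweep the topic count of the topic-model feature
#'
#' Cross-validates every classifier at each K in `config$K_list` on the
#' smallest label set (largest frequency floor) and writes a delimited
#' series of all five measures per (classifier, K), suitable for plotting.
#'
#' @param config an [experiment_config()].
#' @return list with the series data frame and the file path, invisibly.
#' @export
run_topic_sweep <- function(config) {
  sweep_axis(config, "K", config$K_list, "lda",
             function(v, cls) make_pipeline(config, "lda", cls, K = v))
}

#' Sweep the word-vector dimension
#'
#' Cross-validates every classifier at each T in `config$T_list` using
#' mean-pooled skip-gram document vectors on the smallest label set, and
#' writes a delimited series of all five measures per (classifier, T).
#'
#' @param config an [experiment_config()].
#' @return list with the series data frame and the file path, invisibly.
#' @export
run_dim_sweep <- function(config) {
  sweep_axis(config, "T", config$T_list, "word_vector",
             function(v, cls) make_pipeline(config, "word_vector", cls,
                                            T_dim = v))
}
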