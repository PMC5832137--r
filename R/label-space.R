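#' Term-frequency semantic vectorizer for diagnosis labels
#'
#' Maps a label string to a named term-frequency vector over its tokenized
#' components. The default semantic representation behind
#' [label_similarity()]; any function from a string to a nonnegative named
#' vector can be substituted.
#'
#' @param label a single label string.
#' @return named numeric vector of term frequencies.
#' @export
tf_vectorizer <- function(label) {
  toks <- tokenize(label)
  if (length(toks) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(toks)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Semantic similarity between two diagnosis labels
#'
#' Cosine of the two labels' semantic vectors,
#' \eqn{S_s = (S_1 \cdot S_2) / (|S_1| |S_2|)}. Symmetric, bounded in
#' \[0, 1\] for nonnegative vectors, and 1 for identical non-empty labels.
#' A zero vector on either side yields similarity 0 with a warning.
#'
#' @param a,b label strings.
#' @param vectorizer function mapping a label to a nonnegative named vector;
#'   defaults to [tf_vectorizer()].
#' @return similarity in \[0, 1\].
#' @export
label_similarity <- function(a, b, vectorizer = tf_vectorizer) {
  va <- vectorizer(a)
  vb <- vectorizer(b)
  terms <- union(names(va), names(vb))
  x <- stats::setNames(numeric(length(terms)), terms)
  y <- x
  x[names(va)] <- va
  y[names(vb)] <- vb
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero semantic vector; similarity set to 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Merge equivalent diagnosis labels into a standardized label space
#'
#' Different written forms of the same diagnosis (e.g. "state of placenta
#' previa" vs "placenta previa") are merged by single-linkage clustering of
#' pairwise semantic similarity at or above `threshold`. The canonical label
#' of each cluster is its highest-frequency member (ties broken
#' lexicographically). Frequencies are recomputed after merging.
#'
#' @param raw_labels character vector of label occurrences across the corpus
#'   (repetitions determine frequencies).
#' @param threshold similarity threshold in (0, 1].
#' @param vectorizer passed to [label_similarity()].
#' @return a `label_space`: list with `labels` (ordered by decreasing
#'   frequency, ties lexicographic), `freq` (named counts), and `merge_map`
#'   (raw label -> canonical label).
#' @export
merge_labels <- function(raw_labels, threshold = 0.8,
                         vectorizer = tf_vectorizer) {
  stopifnot(threshold > 0, threshold <= 1)
  raw_freq <- table(raw_labels)
  uniq <- names(raw_freq)
  n <- length(uniq)
  comp <- seq_len(n)
  if (n > 1L) {
    vecs <- lapply(uniq, vectorizer)
    find <- function(i) { while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]; i }
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        s <- suppressWarnings(cosine_named(vecs[[i]], vecs[[j]]))
        if (s >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
  }

  canon <- character(n)
  for (g in unique(comp)) {
    members <- uniq[comp == g]
    f <- as.numeric(raw_freq[members])
    canon[comp == g] <- members[order(-f, members)[1L]]
  }
  merge_map <- stats::setNames(canon, uniq)

  merged_freq <- tapply(as.numeric(raw_freq), canon, sum)
  ord <- order(-as.numeric(merged_freq), names(merged_freq))
  labels <- names(merged_freq)[ord]
  freq <- stats::setNames(as.integer(merged_freq[ord]), labels)
  structure(list(labels = labels, freq = freq, merge_map = merge_map),
            class = "label_space")
}

# cosine of two named nonnegative vectors (zero vector -> 0)
cosine_named <- function(va, vb) {
  terms <- union(names(va), names(vb))
  x <- stats::setNames(numeric(length(terms)), terms)
  y <- x
  x[names(va)] <- va
  y[names(vb)] <- vb
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' @export
print.label_space <- function(x, ...) {
  cat(sprintf("label space: %d labels, total frequency %d\n",
              length(x$labels), sum(x$freq)))
  invisible(x)
}

#' Binary instance-by-label matrix for a corpus under a label space
#'
#' Raw diagnosis strings are sent through the space's `merge_map`; raw
#' labels absent from the map are dropped with a warning.
#'
#' @param corpus list of records with `diagnoses`.
#' @param space a `label_space`.
#' @return p x Q binary matrix with column order `space$labels` and row
#'   names the record ids.
#' @export
build_label_matrix <- function(corpus, space) {
  Q <- length(space$labels)
  Y <- matrix(0L, nrow = length(corpus), ncol = Q,
              dimnames = list(vapply(corpus, function(r) as.character(r$id),
                                     character(1)),
                              space$labels))
  unknown <- character(0)
  for (i in seq_along(corpus)) {
    raw <- corpus[[i]]$diagnoses
    mapped <- space$merge_map[raw]
    if (anyNA(mapped)) {
      unknown <- c(unknown, raw[is.na(mapped)])
      mapped <- mapped[!is.na(mapped)]
    }
    Y[i, unique(mapped)] <- 1L
  }
  if (length(unknown))
    warning(sprintf("%d diagnosis occurrence(s) not in the label space were dropped",
                    length(unknown)))
  Y
}

#' Reduce a label space by a corpus-frequency floor
#'
#' Labels whose corpus frequency is below `min_keep_freq` are removed and
#' their columns dropped; instances left with zero labels are removed from
#' the matrix and reported. The floors 2 and 11 are the analogues of the
#' study's reduced label sets (drop singletons; drop frequency <= 10).
#'
#' @param label_matrix binary p x Q matrix in `space` column order.
#' @param space a `label_space`.
#' @param min_keep_freq keep labels with frequency >= this (>= 1).
#' @return list with `matrix`, `space`, and `dropped_instances` (row indices
#'   removed).
#' @export
filter_labels_by_frequency <- function(label_matrix, space, min_keep_freq) {
  stopifnot(min_keep_freq >= 1, ncol(label_matrix) == length(space$labels))
  keep <- space$freq >= min_keep_freq
  if (!any(keep)) stop("frequency floor removes every label")
  labels <- space$labels[keep]
  Y <- label_matrix[, keep, drop = FALSE]
  dropped <- which(rowSums(Y) == 0L)
  if (length(dropped)) Y <- Y[-dropped, , drop = FALSE]
  mm <- space$merge_map[space$merge_map %in% labels]
  reduced <- structure(list(labels = labels,
                            freq = space$freq[keep],
                            merge_map = mm),
                       class = "label_space")
  list(matrix = Y, space = reduced, dropped_instances = dropped)
}

#' Write / read a label space as delimited text
#'
#' The space is stored as a two-column tab-separated table (label,
#' frequency) plus a merge-map table (raw, canonical).
#'
#' @param space a `label_space`.
#' @param path base path; `<path>.labels.tsv` and `<path>.merges.tsv` are
#'   written.
#' @return `path`, invisibly.
#' @export
write_label_space <- function(space, path) {
  utils::write.table(data.frame(label = space$labels,
                                frequency = as.integer(space$freq)),
                     paste0(path, ".labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(raw = names(space$merge_map),
                                canonical = unname(space$merge_map)),
                     paste0(path, ".merges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_space
#' @export
read_label_space <- function(path) {
  lab <- utils::read.table(paste0(path, ".labels.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  mm <- utils::read.table(paste0(path, ".merges.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  structure(list(labels = lab$label,
                 freq = stats::setNames(as.integer(lab$frequency), lab$label),
                 merge_map = stats::setNames(mm$canonical, mm$raw)),
            class = "label_space")
}
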