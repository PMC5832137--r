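#' Deduplicate and clean first-course records
#'
#' Removes exact duplicate records; when several records share an id, keeps
#' the one with the most non-empty sections (information completeness), with
#' the latest `record_time` breaking ties; drops records with no first-course
#' content (all four sections empty); drops temporally inconsistent records
#' whose `record_time` precedes their `reference_time` (e.g. an admission
#' time).
#'
#' @param records list of records; each may carry optional `record_time` and
#'   `reference_time` fields (anything comparable with `<`, e.g. POSIXct or
#'   numeric).
#' @return the retained subset, in original order.
#' @export
deduplicate_first_course <- function(records) {
  if (length(records) == 0L) return(records)

  keys <- vapply(records, function(r) jsonlite::toJSON(r, auto_unbox = TRUE,
                                                       null = "null"),
                 character(1))
  keep <- !duplicated(keys)
  records <- records[keep]

  has_content <- vapply(records, function(r)
    any(vapply(SECTION_KEYS, function(s) length(r[[s]]) > 0, logical(1))),
    logical(1))
  records <- records[has_content]

  consistent <- vapply(records, function(r) {
    if (!is.null(r$record_time) && !is.null(r$reference_time))
      !(r$record_time < r$reference_time)
    else TRUE
  }, logical(1))
  records <- records[consistent]

  if (length(records) == 0L) return(records)
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  completeness <- vapply(records, function(r)
    sum(vapply(SECTION_KEYS, function(s) length(r[[s]]) > 0, logical(1))),
    numeric(1))
  times <- vapply(records, function(r)
    if (is.null(r$record_time)) -Inf else as.numeric(r$record_time),
    numeric(1))

  keep_idx <- vapply(split(seq_along(records), ids), function(ii) {
    ii[order(-completeness[ii], -times[ii], ii)[1L]]
  }, integer(1))
  records[sort(keep_idx)]
}

#' Split raw record text into named sections by heading patterns
#'
#' Text between a matched heading and the next matched heading is assigned
#' to that heading's section, following text order. Unmatched leading text
#' goes to `chief_complaints`; sections whose heading does not occur are
#' empty strings.
#'
#' @param raw_text a single string.
#' @param header_patterns named character vector of regexes; names are the
#'   canonical section keys.
#' @return named list of four section strings.
#' @export
split_sections <- function(raw_text,
                           header_patterns = c(
                             chief_complaints = "(?i)chief complaints?:",
                             physical_exam = "(?i)physical examinations?:",
                             obstetric_exam = "(?i)obstetric examinations?:",
                             auxiliary_exam = "(?i)auxiliary examinations?:")) {
  stopifnot(length(raw_text) == 1L,
            all(names(header_patterns) %in% SECTION_KEYS))
  hits <- do.call(rbind, lapply(names(header_patterns), function(key) {
    m <- gregexpr(header_patterns[[key]], raw_text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(key = key, start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L)
  }))
  if (is.null(hits) || nrow(hits) == 0L)
    stop("no section headings matched; cannot structure record")
  hits <- hits[order(hits$start), , drop = FALSE]

  out <- stats::setNames(as.list(rep("", 4L)), SECTION_KEYS)
  lead <- trimws(substr(raw_text, 1L, hits$start[1] - 1L))
  if (nzchar(lead)) out$chief_complaints <- lead
  for (i in seq_len(nrow(hits))) {
    seg_end <- if (i < nrow(hits)) hits$start[i + 1] - 1L else nchar(raw_text)
    seg <- trimws(substr(raw_text, hits$end[i] + 1L, seg_end))
    key <- hits$key[i]
    out[[key]] <- if (nzchar(out[[key]]))
      paste(out[[key]], seg) else seg
  }
  out
}

#' Tokenize text with greedy longest-match against a term dictionary
#'
#' Multi-word terms in `term_dictionary` are matched greedily (longest match
#' at each position wins); spans not covered by any term are split on
#' whitespace and punctuation. Deterministic.
#'
#' @param text a single string.
#' @param term_dictionary character vector of terms (may be empty).
#' @return character vector of tokens.
#' @export
tokenize <- function(text, term_dictionary = character(0)) {
  stopifnot(length(text) == 1L)
  fallback <- function(chunk) {
    parts <- strsplit(chunk, "[[:space:][:punct:]]+")[[1]]
    parts[nzchar(parts)]
  }
  if (length(term_dictionary) == 0L) return(fallback(text))

  dict <- unique(term_dictionary[nzchar(term_dictionary)])
  dict <- dict[order(-nchar(dict), dict)]
  n <- nchar(text)
  tokens <- character(0)
  buf_start <- 1L
  i <- 1L
  while (i <= n) {
    matched <- NA_character_
    for (term in dict) {
      tl <- nchar(term)
      if (i + tl - 1L <= n && substr(text, i, i + tl - 1L) == term) {
        matched <- term
        break
      }
    }
    if (!is.na(matched)) {
      if (buf_start < i)
        tokens <- c(tokens, fallback(substr(text, buf_start, i - 1L)))
      tokens <- c(tokens, matched)
      i <- i + nchar(matched)
      buf_start <- i
    } else {
      i <- i + 1L
    }
  }
  if (buf_start <= n)
    tokens <- c(tokens, fallback(substr(text, buf_start, n)))
  tokens
}

#' Drop diagnosis strings that are results of a calculation
#'
#' Gestational-age diagnoses ("... pregnancy 28+2 weeks") and gravida/para
#' counts ("pregnancy 3, production 1") are computed from other fields, not
#' inferred, so they are excluded from the class-label candidate set.
#'
#' @param raw_labels character vector of diagnosis strings.
#' @param exclusion_patterns regexes; a label matching any is removed.
#' @return the retained labels.
#' @export
exclude_calculated_labels <- function(raw_labels,
                                      exclusion_patterns = c(
                                        "pregnan(cy|t).*\\bweeks?\\b",
                                        "pregnancy\\s*\\d+.*production\\s*\\d+")) {
  if (length(raw_labels) == 0L) return(raw_labels)
  drop <- Reduce(`|`, lapply(exclusion_patterns, function(p)
    grepl(p, raw_labels, ignore.case = TRUE, perl = TRUE)))
  raw_labels[!drop]
}
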