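#' Normalization rule set
#'
#' Text normalization is an ordered list of pure string rules. The default
#' set case-folds Latin letters, replaces punctuation (Unicode `P*`
#' categories; digits are kept — the N-gram filters need them) with single
#' spaces, collapses runs of horizontal whitespace, and collapses blank
#' lines, trimming each line. Newlines are preserved: they are the sentence
#' delimiter used by [dedup_sentences()].
#'
#' Script-specific character-reordering rules (e.g. misplaced tone marks or
#' vowels in a continuous script) are pluggable: supply them as
#' `list(name = , pattern = , replacement = )` regex rules and they are
#' applied, in order, before punctuation removal. The default set contains
#' none, keeping the core language-agnostic.
#'
#' @param reorder optional list of regex reordering rules as above.
#' @return an ordered list of rules for [normalize_text()].
#' @export
normalization_rules <- function(reorder = list()) {
  rules <- list(list(name = "case_fold", fn = tolower))
  for (r in reorder) {
    .assert(all(c("name", "pattern", "replacement") %in% names(r)),
            "reordering rules need name, pattern, replacement")
    rules <- c(rules, list(list(
      name = r$name,
      fn = local({
        p <- r$pattern; rep <- r$replacement
        function(s) gsub(p, rep, s, perl = TRUE)
      }))))
  }
  c(rules, list(
    list(name = "newline_unify", fn = function(s) gsub("\r\n?", "\n", s)),
    list(name = "punct_to_space",
         fn = function(s) gsub("\\p{P}", " ", s, perl = TRUE)),
    list(name = "collapse_space",
         fn = function(s) gsub("[^\\S\n]+", " ", s, perl = TRUE)),
    list(name = "trim_lines",
         fn = function(s) gsub("(?m)^ +| +$", "", s, perl = TRUE)),
    list(name = "collapse_newlines",
         fn = function(s) gsub("\n(?: *\n)+", "\n", s, perl = TRUE)),
    list(name = "trim",
         fn = function(s) gsub("^\\s+|\\s+$", "", s, perl = TRUE))
  ))
}

#' Normalize free text
#'
#' Applies an ordered rule set (see [normalization_rules()]) to each element
#' of `text`. Idempotent: normalizing already-normalized text is a no-op.
#'
#' @param text character vector.
#' @param rules rule list from [normalization_rules()].
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_text("Chest Pain!!")
normalize_text <- function(text, rules = normalization_rules()) {
  for (r in rules) text <- r$fn(text)
  text
}

.preprocess_report <- function(chars_in, chars_out, duplicates_removed = 0L,
                               corrections_applied = 0L) {
  out <- list(chars_in = chars_in, chars_out = chars_out,
              removal_fraction = if (chars_in > 0) (chars_in - chars_out) / chars_in else 0,
              duplicates_removed = duplicates_removed,
              corrections_applied = corrections_applied)
  class(out) <- "uit_preprocess_report"
  out
}

#' @export
print.uit_preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("<preprocess report> chars %d -> %d (%.2f%% removed), ",
                     "%d duplicate sentences removed, %d corrections\n"),
              x$chars_in, x$chars_out, 100 * x$removal_fraction,
              x$duplicates_removed, x$corrections_applied))
  invisible(x)
}

.corpus_nchar <- function(x) {
  sum(nchar(x$chief_complaint, type = "chars")) +
    sum(nchar(x$present_illness, type = "chars"))
}

#' Normalize every text section of a corpus
#'
#' @param x a `uit_corpus`.
#' @param rules rule list from [normalization_rules()].
#' @return the corpus with both sections normalized.
#' @export
normalize_corpus <- function(x, rules = normalization_rules()) {
  validate_corpus(x)
  x$chief_complaint <- normalize_text(x$chief_complaint, rules)
  x$present_illness <- normalize_text(x$present_illness, rules)
  x
}

#' Remove sentences repeated from a patient's earlier documents
#'
#' Clinicians routinely copy sentences forward from prior visits; counting
#' such copies would inflate term frequencies. Within each patient, taking
#' documents in corpus order, a sentence (newline-delimited line) identical
#' to one seen in an *earlier* document of the same patient is dropped; the
#' first occurrence is always kept, and documents of different patients never
#' affect each other. With `granularity = "entry"` whole text sections are
#' compared instead of sentences.
#'
#' @param x a (normalized) `uit_corpus`.
#' @param granularity `"sentence"` (default) or `"entry"`.
#' @return `list(corpus = , report = )`; the report counts removed sentences
#'   and the character removal fraction.
#' @export
dedup_sentences <- function(x, granularity = c("sentence", "entry")) {
  validate_corpus(x, allow_empty = TRUE)
  granularity <- match.arg(granularity)
  chars_in <- .corpus_nchar(x)
  removed <- 0L
  for (pid in unique(x$patient_id)) {
    idx <- which(x$patient_id == pid)
    seen <- new.env(parent = emptyenv())
    for (i in idx) {
      for (col in c("chief_complaint", "present_illness")) {
        txt <- x[[col]][i]
        units <- if (granularity == "sentence") {
          strsplit(txt, "\n", fixed = TRUE)[[1]]
        } else if (nzchar(txt)) txt else character(0)
        if (length(units) == 0) next
        keys <- trimws(units)
        dup <- nzchar(keys) &
          vapply(keys, function(k) !is.null(seen[[k]]), logical(1))
        removed <- removed + sum(dup)
        x[[col]][i] <- paste(units[!dup], collapse = "\n")
      }
      # only after the whole document is processed does it seed the pool,
      # so within-document repeats are untouched
      for (col in c("chief_complaint", "present_illness")) {
        kept <- if (granularity == "sentence") {
          strsplit(x[[col]][i], "\n", fixed = TRUE)[[1]]
        } else x[[col]][i]
        for (k in trimws(kept)) {
          if (nzchar(k)) assign(k, TRUE, envir = seen)
        }
      }
    }
  }
  list(corpus = x,
       report = .preprocess_report(chars_in, .corpus_nchar(x),
                                   duplicates_removed = removed))
}

#' Apply dictionary spell checking to a corpus
#'
#' Each space-delimited token of every (already normalized) text section is
#' passed through [spell_correct()]; continuous-script runs and short tokens
#' are never altered. The corrections actually applied are returned in the
#' report and as its `corrections` attribute (a before/after table).
#'
#' @param x a normalized `uit_corpus`.
#' @param lexicon a `uit_lexicon`.
#' @param max_edit maximum edit distance for a correction (default 1).
#' @return `list(corpus = , report = )`.
#' @export
apply_spell_check <- function(x, lexicon, max_edit = 1) {
  validate_corpus(x, allow_empty = TRUE)
  chars_in <- .corpus_nchar(x)
  all_text <- c(x$chief_complaint, x$present_illness)
  toks <- unique(unlist(strsplit(all_text, "[ \n]+"), use.names = FALSE))
  toks <- toks[nzchar(toks)]
  fixed <- .spell_correct_many(toks, lexicon, max_edit)
  changed <- fixed != toks
  map <- new.env(parent = emptyenv())
  for (i in which(changed)) assign(toks[i], fixed[i], envir = map)
  n_corr <- 0L
  substitute_tokens <- function(txt) {
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- vapply(lines, function(ln) {
      ws <- strsplit(ln, " ", fixed = TRUE)[[1]]
      for (j in seq_along(ws)) {
        rep <- map[[ws[j]]]
        if (!is.null(rep)) {
          ws[j] <- rep
          n_corr <<- n_corr + 1L
        }
      }
      paste(ws, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
    paste(lines, collapse = "\n")
  }
  if (any(changed)) {
    x$chief_complaint <- vapply(x$chief_complaint, substitute_tokens,
                                character(1), USE.NAMES = FALSE)
    x$present_illness <- vapply(x$present_illness, substitute_tokens,
                                character(1), USE.NAMES = FALSE)
  }
  rep <- .preprocess_report(chars_in, .corpus_nchar(x),
                            corrections_applied = n_corr)
  attr(rep, "corrections") <- data.frame(from = toks[changed],
                                         to = fixed[changed],
                                         stringsAsFactors = FALSE)
  list(corpus = x, report = rep)
}
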