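#' Tokenizer configuration
#'
#' @param unknown_fallback what to emit when no dictionary entry matches at a
#'   position: `"merge_run"` (default) merges the maximal run of unmatched
#'   same-script characters into one out-of-dictionary token, `"single_char"`
#'   emits one token per character.
#' @param allow_multiword_entries when `TRUE` (default), dictionary entries
#'   containing internal spaces (multiword clinical jargon from concept
#'   descriptions) may match across spaces; whitespace is otherwise always a
#'   token boundary and never emitted.
#' @param script_change_is_boundary treat a change of script class (e.g.
#'   continuous to Latin) like whitespace when merging unknown runs
#'   (default `TRUE`).
#' @return a `uit_tokenizer_config` list.
#' @export
tokenizer_config <- function(unknown_fallback = c("merge_run", "single_char"),
                             allow_multiword_entries = TRUE,
                             script_change_is_boundary = TRUE) {
  out <- list(unknown_fallback = match.arg(unknown_fallback),
              allow_multiword_entries = isTRUE(allow_multiword_entries),
              script_change_is_boundary = isTRUE(script_change_is_boundary))
  class(out) <- "uit_tokenizer_config"
  out
}

#' Classify the script of a token surface
#'
#' `continuous` if the surface has at least one continuous-script code point
#' (Thai block or the synthetic private-use block) and no Latin letter;
#' `latin` if it has only Latin letters; `mixed` if it has both continuous
#' and Latin; `digit` if it has only digits; `other` otherwise.
#'
#' @param surfaces non-empty character vector of token surfaces.
#' @return character vector over
#'   `c("continuous", "latin", "mixed", "digit", "other")`.
#' @export
#' @examples
#' classify_script(c("copd", "123"))
classify_script <- function(surfaces) {
  .assert(all(nzchar(surfaces)), "cannot classify an empty surface")
  vapply(surfaces, function(s) {
    cp <- utf8ToInt(s)
    has_cont <- any(.is_continuous_cp(cp))
    is_lat <- (cp >= 0x41 & cp <= 0x5A) | (cp >= 0x61 & cp <= 0x7A)
    is_dig <- cp >= 0x30 & cp <= 0x39
    if (has_cont && any(is_lat)) "mixed"
    else if (has_cont) "continuous"
    else if (all(is_lat)) "latin"
    else if (all(is_dig)) "digit"
    else "other"
  }, character(1), USE.NAMES = FALSE)
}

# script class of one code point, for unknown-run merging
.char_class <- function(cp) {
  ifelse(.is_continuous_cp(cp), "continuous",
         ifelse((cp >= 0x41 & cp <= 0x5A) | (cp >= 0x61 & cp <= 0x7A), "latin",
                ifelse(cp >= 0x30 & cp <= 0x39, "digit", "other")))
}

#' Maximum-matching segmentation of mixed-script text
#'
#' Greedy longest-match segmentation against the dictionary: scanning left to
#' right, at each position all dictionary entries matching there are
#' considered and the longest is emitted; scanning resumes after it. When no
#' entry matches, the fallback policy of `config` emits an out-of-dictionary
#' token. Whitespace is consumed as a boundary and never emitted. Offsets are
#' 0-based, half-open, in characters of `text`, so the segmentation is
#' auditable against the source: the token surfaces plus skipped whitespace
#' reconstruct the input exactly.
#'
#' @param text a single (normalized) string.
#' @param lexicon a `uit_lexicon`; matching is exact on the match key, so the
#'   text must already be case-normalized.
#' @param config a [tokenizer_config()].
#' @return data frame with columns `surface`, `start`, `end`, `script`,
#'   `in_dictionary`, one row per token in order.
#' @export
#' @examples
#' lex <- build_lexicon(list(custom = c("ab", "abc", "c", "d")))
#' max_match_tokenize("abcd", lex)$surface # "abc", "d"
max_match_tokenize <- function(text, lexicon, config = tokenizer_config()) {
  .assert(inherits(lexicon, "uit_lexicon") && nrow(lexicon$entries) > 0,
          "max_match_tokenize needs a non-empty lexicon")
  .assert(length(text) == 1, "text must be a single string")
  n <- nchar(text, type = "chars")
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), script = character(0),
                      in_dictionary = logical(0))
  if (n == 0) return(empty)
  cp <- utf8ToInt(text)
  is_ws <- cp %in% c(0x20L, 0x09L, 0x0AL, 0x0DL)
  cls <- .char_class(cp)
  surfs <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  known <- logical(0)
  j <- 1L
  while (j <= n) {
    if (is_ws[j]) {
      j <- j + 1L
      next
    }
    first <- substr(text, j, j)
    lens <- lexicon$index[[first]]
    matched <- 0L
    if (!is.null(lens)) {
      for (len in lens) {
        if (len > n - j + 1L) next
        end <- j + len - 1L
        cand <- substr(text, j, end)
        if (grepl(" ", cand, fixed = TRUE)) {
          if (!config$allow_multiword_entries) next
          # multiword candidates must not swallow newlines or double spaces
          if (any(is_ws[j:end] & cp[j:end] != 0x20L)) next
        }
        if (!is.null(lexicon$env[[cand]])) {
          matched <- len
          break
        }
      }
    }
    if (matched > 0L) {
      end <- j + matched - 1L
      surfs <- c(surfs, substr(text, j, end))
      starts <- c(starts, j - 1L)
      ends <- c(ends, end)
      known <- c(known, TRUE)
      j <- end + 1L
    } else if (config$unknown_fallback == "single_char") {
      surfs <- c(surfs, first)
      starts <- c(starts, j - 1L)
      ends <- c(ends, j)
      known <- c(known, FALSE)
      j <- j + 1L
    } else {
      # merge the maximal run of unmatched characters: stop at whitespace,
      # at a script-class change (if configured), or where a match begins
      k <- j
      while (k < n) {
        nxt <- k + 1L
        if (is_ws[nxt]) break
        if (config$script_change_is_boundary && cls[nxt] != cls[j]) break
        if (.match_exists_at(text, nxt, n, is_ws, lexicon, config)) break
        k <- nxt
      }
      surfs <- c(surfs, substr(text, j, k))
      starts <- c(starts, j - 1L)
      ends <- c(ends, k)
      known <- c(known, FALSE)
      j <- k + 1L
    }
  }
  data.frame(surface = surfs, start = starts, end = ends,
             script = classify_script(surfs), in_dictionary = known,
             stringsAsFactors = FALSE)
}

# is there any dictionary match starting at position j (1-based)?
.match_exists_at <- function(text, j, n, is_ws, lexicon, config) {
  lens <- lexicon$index[[substr(text, j, j)]]
  if (is.null(lens)) return(FALSE)
  for (len in lens) {
    if (len > n - j + 1L) next
    end <- j + len - 1L
    cand <- substr(text, j, end)
    if (grepl(" ", cand, fixed = TRUE) && !config$allow_multiword_entries) next
    if (!is.null(lexicon$env[[cand]])) return(TRUE)
  }
  FALSE
}

#' Tokenize every document of a corpus
#'
#' Runs [max_match_tokenize()] on each text section of each document. The two
#' sections are segmented independently (candidate terms never span the
#' chief-complaint / present-illness boundary), as are newline-delimited
#' sentences.
#'
#' @param x a normalized `uit_corpus`.
#' @param lexicon a `uit_lexicon`.
#' @param config a [tokenizer_config()].
#' @return list parallel to the corpus rows; each element a token data frame
#'   with an extra `section` column (`"cc"` or `"pi"`) and `sentence` index,
#'   usable directly by [compute_corpus_stats()] and [generate_ngrams()].
#' @export
tokenize_corpus <- function(x, lexicon, config = tokenizer_config()) {
  validate_corpus(x, allow_empty = TRUE)
  lapply(seq_len(nrow(x)), function(i) {
    parts <- list()
    for (sec in c(cc = "chief_complaint", pi = "present_illness")) {
      lines <- strsplit(x[[sec]][i], "\n", fixed = TRUE)[[1]]
      for (s in seq_along(lines)) {
        if (!nzchar(lines[s])) next
        tk <- max_match_tokenize(lines[s], lexicon, config)
        if (nrow(tk) == 0) next
        tk$section <- if (sec == "chief_complaint") "cc" else "pi"
        tk$sentence <- s
        parts[[length(parts) + 1L]] <- tk
      }
    }
    if (length(parts) == 0) {
      out <- data.frame(surface = character(0), start = integer(0),
                        end = integer(0), script = character(0),
                        in_dictionary = logical(0), section = character(0),
                        sentence = integer(0))
    } else {
      out <- do.call(rbind, parts)
    }
    rownames(out) <- NULL
    out
  })
}
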