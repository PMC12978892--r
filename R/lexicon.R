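#' Build the custom segmentation dictionary
#'
#' The dictionary used for both spell checking and maximum-matching
#' segmentation is the union of several word-list sources: a general English
#' word net, a general local-language (continuous-script) word net, concept
#' descriptions from the reference terminology (which contribute multiword
#' clinical jargon), a drug terminology, and a reviewed abbreviation list.
#' Entries are deduplicated on a match key: Latin letters are case-folded
#' (continuous scripts have no case, so those entries are kept verbatim); the
#' first source to contribute an entry keeps the tag.
#'
#' @param sources named list. Names are source tags, one of `wordnet_en`,
#'   `wordnet_local`, `concept_descriptions`, `drug_db`, `abbreviations`,
#'   `custom`; repeats allowed. Each element is either a path to a UTF-8
#'   word-list file (one term per line, `#` comments and blank lines ignored)
#'   or a character vector of terms.
#' @return a `uit_lexicon`: entry table plus the first-character length index
#'   that supports longest-match scanning.
#' @export
#' @examples
#' lex <- build_lexicon(list(wordnet_en = c("fever", "chest pain"),
#'                           drug_db = c("paracetamol")))
#' lexicon_contains(lex, c("Fever", "aspirin"))
build_lexicon <- function(sources) {
  .assert(length(sources) > 0, "no lexicon sources given")
  tags <- names(sources)
  .assert(!is.null(tags) && all(nzchar(tags)), "every source needs a tag name")
  known <- c("wordnet_en", "wordnet_local", "concept_descriptions",
             "drug_db", "abbreviations", "custom")
  bad <- setdiff(tags, known)
  .assert(length(bad) == 0, "unknown source tag(s): %s", paste(bad, collapse = ", "))
  surf <- character(0)
  src <- character(0)
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    if (is.character(s) && length(s) == 1 && file.exists(s)) {
      s <- readLines(s, encoding = "UTF-8", warn = FALSE)
      s <- s[!grepl("^\\s*#", s)]
    }
    s <- trimws(as.character(s))
    s <- s[nzchar(s)]
    surf <- c(surf, s)
    src <- c(src, rep(tags[i], length(s)))
  }
  .assert(length(surf) > 0,
          "empty lexicon union: the tokenizer would degenerate to character emission")
  key <- lexicon_key(surf)
  keep <- !duplicated(key)
  entries <- data.frame(surface = surf[keep], key = key[keep],
                        source = src[keep],
                        is_abbreviation = src[keep] == "abbreviations",
                        stringsAsFactors = FALSE)
  .lexicon_build_index(entries)
}

#' @rdname build_lexicon
#' @param surfaces character vector of entry surfaces.
#' @return `lexicon_key()`: the case-folded match key for each surface.
#' @export
lexicon_key <- function(surfaces) tolower(surfaces)

.lexicon_build_index <- function(entries) {
  env <- new.env(parent = emptyenv(), size = max(32L, 2L * nrow(entries)))
  for (i in seq_len(nrow(entries))) assign(entries$key[i], i, envir = env)
  nch <- nchar(entries$key, type = "chars")
  first <- substr(entries$key, 1, 1)
  index <- lapply(split(nch, first), function(l) sort(unique(l), decreasing = TRUE))
  lex <- list(entries = entries, env = env, index = index,
              max_entry_length = max(nch))
  class(lex) <- "uit_lexicon"
  lex
}

#' @rdname build_lexicon
#' @param lexicon a `uit_lexicon`.
#' @param terms character vector to test.
#' @return `lexicon_contains()`: logical vector of membership (by match key).
#' @export
lexicon_contains <- function(lexicon, terms) {
  vapply(lexicon_key(terms), function(k) !is.null(lexicon$env[[k]]),
         logical(1), USE.NAMES = FALSE)
}

#' @export
print.uit_lexicon <- function(x, ...) {
  cat(sprintf("<uit_lexicon> %d entries (max length %d) from sources: %s\n",
              nrow(x$entries), x$max_entry_length,
              paste(sort(unique(x$entries$source)), collapse = ", ")))
  invisible(x)
}

#' Harvest abbreviation candidates from raw text
#'
#' Scans the corpus, before any case normalization, for whitespace- and
#' punctuation-delimited tokens containing at least `min_capitals` capital
#' Latin letters that occur strictly more than `min_frequency` times in the
#' whole dataset. These are candidates only: acceptance is a clinical review
#' step recorded externally (see the `accepted` column, initialized `NA`).
#'
#' @param x a `uit_corpus` holding raw (unnormalized) text.
#' @param min_capitals minimum number of capital letters (default 2).
#' @param min_frequency frequency threshold, exclusive (default 100: a
#'   candidate must occur more than 100 times).
#' @return data frame `surface`, `n_capitals`, `corpus_frequency`, `accepted`,
#'   sorted by frequency descending.
#' @export
harvest_abbreviations <- function(x, min_capitals = 2, min_frequency = 100) {
  validate_corpus(x)
  text <- c(x$chief_complaint, x$present_illness)
  toks <- unlist(strsplit(text, "[^\\p{L}\\p{N}]+", perl = TRUE), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    return(data.frame(surface = character(0), n_capitals = integer(0),
                      corpus_frequency = integer(0), accepted = logical(0)))
  }
  ncap <- nchar(gsub("[^A-Z]", "", toks))
  toks <- toks[ncap >= min_capitals]
  tab <- table(toks)
  tab <- tab[tab > min_frequency]
  if (length(tab) == 0) {
    return(data.frame(surface = character(0), n_capitals = integer(0),
                      corpus_frequency = integer(0), accepted = logical(0)))
  }
  out <- data.frame(surface = names(tab),
                    n_capitals = nchar(gsub("[^A-Z]", "", names(tab))),
                    corpus_frequency = as.integer(tab),
                    accepted = NA,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$corpus_frequency, out$surface), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an abbreviation review file
#'
#' Clinical reviewers return the harvested candidates with an accept/reject
#' decision; accepted surfaces are what gets merged into the dictionary.
#'
#' @param path tab-separated file with columns `surface`, `corpus_frequency`,
#'   `accepted` (`yes`/`no`) and optional `expansion`.
#' @return data frame with a logical `accepted` column.
#' @export
read_abbreviation_review <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  .assert(all(c("surface", "accepted") %in% names(df)),
          "review file needs columns surface, accepted")
  df$accepted <- tolower(trimws(as.character(df$accepted))) %in% c("yes", "y", "true", "1")
  df
}

# latin-only keys and their lengths, memoised per lexicon via local attr
.latin_keys <- function(lexicon) {
  keys <- lexicon$entries$key
  lat <- grepl("^[a-z]+$", keys)
  list(keys = keys[lat], nch = nchar(keys[lat]), surf = lexicon$entries$surface[lat])
}

#' Spell-correct a token against the dictionary
#'
#' A non-continuous-script token is returned unchanged when it is in the
#' dictionary; otherwise, when exactly one dictionary entry lies within
#' `max_edit` Levenshtein operations, that entry is returned; with zero or
#' several candidates the token is returned unchanged (ambiguous corrections
#' are unsafe). Tokens shorter than 4 characters and tokens containing
#' continuous-script characters are never altered.
#'
#' @param token a single token (already whitespace-delimited).
#' @param lexicon a `uit_lexicon`.
#' @param max_edit maximum edit distance (default 1).
#' @return the corrected (or original) token.
#' @export
spell_correct <- function(token, lexicon, max_edit = 1) {
  .spell_correct_many(token, lexicon, max_edit)[1]
}

# vectorized over unique tokens; used by apply_spell_check
.spell_correct_many <- function(tokens, lexicon, max_edit = 1) {
  out <- tokens
  elig <- nchar(tokens) >= 4 & !.has_continuous(tokens) &
    !lexicon_contains(lexicon, tokens)
  if (!any(elig)) return(out)
  lat <- .latin_keys(lexicon)
  if (length(lat$keys) == 0) return(out)
  for (i in which(elig)) {
    key <- lexicon_key(tokens[i])
    near <- which(abs(lat$nch - nchar(key)) <= max_edit)
    if (length(near) == 0) next
    d <- utils::adist(key, lat$keys[near])[1, ]
    hit <- near[d <= max_edit]
    if (length(hit) == 1) out[i] <- lat$surf[hit]
  }
  out
}
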