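#' Selection configuration for candidate terms
#'
#' The thresholds driving interface-term selection: N-grams of length 1-5, a
#' candidate is syntactically filtered when more than half of its tokens are
#' stop words, pure punctuation or pure numbers, or when it begins or ends
#' with a stop word or preposition; a surviving candidate is selected when
#' its frequency rank falls within the top 70% of its N-stratum or its
#' absolute frequency is at least 300.
#'
#' @param n_max maximum N-gram length (default 5).
#' @param stopword_fraction_max maximum tolerated stop/punct/number token
#'   fraction, exclusive (default 0.5).
#' @param percentile_cut rank-percentile cut, inclusive (default 70: rank
#'   within the first 70% of the stratum).
#' @param frequency_cut absolute frequency cut, inclusive (default 300).
#' @param stopwords,prepositions character vectors of stop resources; the
#'   defaults are small English lists, see [default_stopwords()].
#' @return a `uit_selection_config` list.
#' @export
selection_config <- function(n_max = 5, stopword_fraction_max = 0.5,
                             percentile_cut = 70, frequency_cut = 300,
                             stopwords = default_stopwords(),
                             prepositions = default_prepositions()) {
  .assert(n_max >= 1 && percentile_cut > 0 && frequency_cut > 0,
          "selection thresholds must be positive")
  out <- list(n_max = as.integer(n_max),
              stopword_fraction_max = stopword_fraction_max,
              percentile_cut = percentile_cut,
              frequency_cut = frequency_cut,
              stopwords = unique(tolower(stopwords)),
              prepositions = unique(tolower(prepositions)))
  class(out) <- "uit_selection_config"
  out
}

#' Default stop-word and preposition lists
#'
#' Small Latin-script lists covering the function words that dominate
#' clinical free text. Real-language deployments supply their own resources
#' through [selection_config()]; the synthetic study generator appends its
#' own planted stop words.
#'
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "if", "then", "than", "so",
    "no", "not", "yes", "is", "am", "are", "was", "were", "be", "been",
    "has", "have", "had", "do", "does", "did", "this", "that", "these",
    "those", "it", "its", "he", "she", "they", "i", "we", "you",
    default_prepositions())
}

#' @rdname default_stopwords
#' @export
default_prepositions <- function() {
  c("of", "in", "on", "at", "to", "for", "with", "by", "from", "about",
    "into", "over", "under", "after", "before", "during", "per", "via")
}

#' Generate N-gram candidate terms from tokenized documents
#'
#' All overlapping windows of 1..`n_max` consecutive tokens are counted,
#' within each document section and sentence (never across documents,
#' sections or sentence boundaries); the frequency of a candidate is its
#' total occurrence count over the corpus.
#'
#' @param tokens_per_doc list of token data frames from [tokenize_corpus()]
#'   (or plain character vectors of token surfaces).
#' @param n_max maximum window length (default 5).
#' @return a `uit_candidates` data frame: `surface` (tokens joined by a
#'   space), `n`, `frequency`, plus the bookkeeping columns `filtered_reason`,
#'   `rank_within_n`, `percentile_within_n`, `selected`, `review_status`
#'   initialized for the downstream steps.
#' @export
#' @examples
#' generate_ngrams(list(c("a", "b", "a", "b")), n_max = 2)
generate_ngrams <- function(tokens_per_doc, n_max = 5) {
  .assert(n_max >= 1, "n_max must be at least 1")
  counts <- new.env(parent = emptyenv(), size = 4096L)
  bump <- function(keys) {
    for (k in keys) {
      v <- counts[[k]]
      counts[[k]] <- if (is.null(v)) 1L else v + 1L
    }
  }
  for (doc in tokens_per_doc) {
    if (is.data.frame(doc)) {
      if (nrow(doc) == 0) next
      grp <- paste(doc$section %||% "x", doc$sentence %||% 1L)
      runs <- split(as.character(doc$surface), factor(grp, unique(grp)))
    } else {
      if (length(doc) == 0) next
      runs <- list(as.character(doc))
    }
    for (toks in runs) {
      len <- length(toks)
      for (n in seq_len(min(n_max, len))) {
        if (n == 1L) {
          bump(toks)
        } else {
          windows <- vapply(seq_len(len - n + 1L), function(s)
            paste(toks[s:(s + n - 1L)], collapse = " "), character(1))
          bump(windows)
        }
      }
    }
  }
  keys <- ls(counts, sorted = TRUE)
  freq <- vapply(keys, function(k) counts[[k]], integer(1), USE.NAMES = FALSE)
  ngram_n <- lengths(strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(surface = keys, n = as.integer(ngram_n),
                    frequency = freq,
                    filtered_reason = NA_character_,
                    rank_within_n = NA_integer_,
                    percentile_within_n = NA_real_,
                    selected = FALSE,
                    review_status = "pending",
                    stringsAsFactors = FALSE)
  class(out) <- c("uit_candidates", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_stopish <- function(tokens, config) {
  tolower(tokens) %in% config$stopwords |
    grepl("^\\p{P}+$", tokens, perl = TRUE) |
    grepl("^[0-9]+$", tokens)
}

#' Filter syntactically irrelevant candidates
#'
#' Marks candidates whose stop-word/punctuation/number token fraction exceeds
#' the configured maximum (`filtered_reason = "stopword_fraction"`), or whose
#' first or last token is a stop word (`"boundary_stopword"`) or preposition
#' (`"boundary_preposition"`). Surviving candidates keep `filtered_reason`
#' `NA`. Filtered candidates are never selected.
#'
#' @param candidates a `uit_candidates` data frame.
#' @param config a [selection_config()].
#' @return the candidates with `filtered_reason` set.
#' @export
filter_candidates <- function(candidates, config = selection_config()) {
  toks <- strsplit(candidates$surface, " ", fixed = TRUE)
  reason <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    tt <- toks[[i]]
    frac <- sum(.is_stopish(tt, config)) / length(tt)
    edge <- tolower(c(tt[1], tt[length(tt)]))
    if (frac > config$stopword_fraction_max) {
      reason[i] <- "stopword_fraction"
    } else if (any(edge %in% config$prepositions)) {
      reason[i] <- "boundary_preposition"
    } else if (any(edge %in% config$stopwords)) {
      reason[i] <- "boundary_stopword"
    }
  }
  candidates$filtered_reason <- reason
  candidates$selected <- candidates$selected & is.na(reason)
  candidates
}

#' Rank surviving candidates within each N-stratum
#'
#' Within each N, surviving (unfiltered) candidates are sorted by frequency
#' descending, ties broken lexicographically by surface for determinism;
#' rank 1 is the most frequent, and the rank percentile is
#' `100 * rank / stratum size`. Filtered candidates keep `NA` rank.
#'
#' @param candidates filtered `uit_candidates`.
#' @return the candidates with `rank_within_n` and `percentile_within_n` set.
#' @export
rank_candidates <- function(candidates) {
  candidates$rank_within_n <- NA_integer_
  candidates$percentile_within_n <- NA_real_
  for (n in sort(unique(candidates$n))) {
    idx <- which(candidates$n == n & is.na(candidates$filtered_reason))
    if (length(idx) == 0) next
    ord <- idx[order(-candidates$frequency[idx], candidates$surface[idx],
                     method = "radix")]
    candidates$rank_within_n[ord] <- seq_along(ord)
    candidates$percentile_within_n[ord] <- 100 * seq_along(ord) / length(ord)
  }
  candidates
}

#' Select interface-term candidates
#'
#' A candidate is selected exactly when it is unfiltered and its rank
#' percentile is at most `percentile_cut` *or* its frequency is at least
#' `frequency_cut`.
#'
#' @param candidates ranked `uit_candidates`.
#' @param config a [selection_config()].
#' @return the candidates with `selected` set.
#' @export
select_terms <- function(candidates, config = selection_config()) {
  ok <- is.na(candidates$filtered_reason) &
    (candidates$percentile_within_n <= config$percentile_cut |
       candidates$frequency >= config$frequency_cut)
  candidates$selected <- !is.na(ok) & ok
  candidates
}

#' Export / import the clinical review sheet
#'
#' Selected candidates go out to clinical reviewers as a delimited sheet;
#' decisions come back as `accepted` / `rejected` per surface. The final
#' interface terminology is the set of candidates that are both selected and
#' accepted. The sheet round-trips every candidate field.
#'
#' @param candidates a `uit_candidates` data frame (selection done).
#' @param path file path (tab-separated, UTF-8).
#' @return `export_review_sheet()` returns `path` invisibly;
#'   `import_review_decisions()` returns the candidates with `review_status`
#'   updated (error if the sheet names an unknown candidate).
#' @export
export_review_sheet <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname export_review_sheet
#' @export
import_review_decisions <- function(candidates, path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8", na.strings = "")
  .assert(all(c("surface", "review_status") %in% names(sheet)),
          "review sheet needs columns surface, review_status")
  unknown <- setdiff(sheet$surface, candidates$surface)
  .assert(length(unknown) == 0, "decision(s) for unknown candidate(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  m <- match(candidates$surface, sheet$surface)
  st <- sheet$review_status[m]
  st[is.na(st)] <- "pending"
  .assert(all(st %in% c("pending", "accepted", "rejected")),
          "review_status must be pending/accepted/rejected")
  candidates$review_status <- st
  candidates
}

#' Final interface terminology from reviewed candidates
#'
#' @param candidates reviewed `uit_candidates`.
#' @return the subset that is selected and accepted.
#' @export
final_terms <- function(candidates) {
  candidates[candidates$selected & candidates$review_status == "accepted", ,
             drop = FALSE]
}
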