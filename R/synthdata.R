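#' Design of a synthetic terminology-harvesting study
#'
#' Bundles every knob of the synthetic study generator. The defaults emulate,
#' at desk scale, the statistical structure of a bilingual three-department
#' outpatient corpus: internal medicine contributes most documents but the
#' lowest continuous-script share, term frequencies follow a Zipf law, some
#' sentences are copied forward between a patient's visits, a small fraction
#' of Latin tokens is misspelled, and the concept catalog covers the planted
#' terms at designed equivalence-category fractions.
#'
#' @param seed integer seed; every random choice of the generator flows from
#'   it.
#' @param departments data frame with `department`, `n_patients`,
#'   `n_documents`, `script_mix` (continuous-script word fraction) and
#'   `words_per_doc` (mean document length in tokens).
#' @param n_terms number of planted clinical terms (default 220).
#' @param prop_thai fraction of planted terms in the synthetic continuous
#'   script (default 0.45, the rest Latin).
#' @param ngram_weights probabilities of term gram-lengths 1..5.
#' @param zipf_scale,zipf_exponent designed frequency of the rank-r term is
#'   `round(zipf_scale / r^zipf_exponent)` (at least 1).
#' @param equivalence_fractions named fractions over
#'   full/broader/narrower/inexact/unmapped map entries; must sum to 1.
#' @param unmapped_fractions named fractions over
#'   ambiguous/multiconcept/no_concept within the unmapped subset.
#' @param one_to_many_fraction fraction of mapped terms mapped to two
#'   concepts instead of one.
#' @param concept_reuse_fraction fraction of mapped entries that point to an
#'   already-used concept (drives the unique-concept count below the mapped
#'   entry count).
#' @param direct_match_fraction fraction of map entries whose source term has
#'   a catalog description with the same word multiset (Latin terms only:
#'   the catalog carries no continuous-script descriptions).
#' @param duplicate_sentence_rate expected copied-forward sentences per
#'   original sentence in a patient's later documents.
#' @param misspelling_rate fraction of eligible Latin token instances
#'   corrupted by one edit.
#' @param stopword_filler_rate fraction of Latin filler tokens drawn from the
#'   stop-word list.
#' @param n_abbreviations,abbreviation_frequency capitalized abbreviations
#'   planted in the raw text, each occurring `abbreviation_frequency` times
#'   (> 100, so the harvesting rule finds them).
#' @return a `uit_study_design` list.
#' @export
study_design <- function(
    seed = 1L,
    departments = data.frame(
      department = c("FM", "ER", "IM"),
      n_patients = c(40L, 60L, 80L),
      n_documents = c(60L, 70L, 230L),
      script_mix = c(0.59, 0.637, 0.397),
      words_per_doc = c(60, 74, 107),
      stringsAsFactors = FALSE),
    n_terms = 220L,
    prop_thai = 0.45,
    ngram_weights = c(0.53, 0.36, 0.09, 0.015, 0.005),
    zipf_scale = 2000,
    zipf_exponent = 1.1,
    equivalence_fractions = c(full = 0.855, broader = 0.059,
                              narrower = 0.027, inexact = 0.039,
                              unmapped = 0.020),
    unmapped_fractions = c(ambiguous = 0.548, multiconcept = 0.238,
                           no_concept = 0.214),
    one_to_many_fraction = 0.014,
    concept_reuse_fraction = 0.03,
    direct_match_fraction = 0.315,
    duplicate_sentence_rate = 0.10,
    misspelling_rate = 0.01,
    stopword_filler_rate = 0.30,
    n_abbreviations = 3L,
    abbreviation_frequency = 150L) {
  .assert(abs(sum(equivalence_fractions) - 1) < 1e-8,
          "equivalence_fractions must sum to 1")
  .assert(all(names(equivalence_fractions) == .equivalences),
          "equivalence_fractions must be named full/broader/narrower/inexact/unmapped")
  .assert(abs(sum(unmapped_fractions) - 1) < 1e-8,
          "unmapped_fractions must sum to 1")
  out <- as.list(environment())
  out$ngram_weights <- ngram_weights / sum(ngram_weights)
  class(out) <- "uit_study_design"
  out
}

# run code under a local RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# integer allocation of `total` over fractions by largest remainder
.largest_remainder <- function(fracs, total) {
  raw <- fracs * total
  base <- floor(raw)
  rem <- raw - base
  short <- total - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  out <- as.integer(base)
  names(out) <- names(fracs)
  out
}

# ---- synthetic language ----------------------------------------------------

# continuous-script units: one head code point (U+E000..U+E03F) followed by
# 1..3 tail code points (U+E040..U+E0BF); the head/tail split makes maximum
# matching provably recover the planted unit segmentation
.make_units <- function(n) {
  heads <- 0xE000L + 0:63
  tails <- 0xE040L + 0:127
  seen <- new.env(parent = emptyenv())
  out <- character(n)
  i <- 1L
  while (i <= n) {
    u <- intToUtf8(c(sample(heads, 1), sample(tails, sample(1:3, 1), replace = TRUE)))
    if (is.null(seen[[u]])) {
      seen[[u]] <- TRUE
      out[i] <- u
      i <- i + 1L
    }
  }
  out
}

# latin pseudo-words, pairwise Levenshtein distance >= 3 from each other and
# from the reserved words, so a 1-edit misspelling always has a unique
# correction
.make_jargon <- function(n, reserved = character(0)) {
  out <- character(0)
  guard <- c(reserved)
  while (length(out) < n) {
    w <- paste(sample(letters, sample(6:9, 1), replace = TRUE), collapse = "")
    if (length(guard) == 0 || min(utils::adist(w, guard)) >= 3) {
      out <- c(out, w)
      guard <- c(guard, w)
    }
  }
  out
}

# ---- study generation ------------------------------------------------------

#' Generate a complete synthetic study
#'
#' Deterministically (given the design seed) builds a synthetic language, a
#' corpus with planted clinical terms at designed Zipfian frequencies,
#' word-list lexicon sources, an RF2-style concept catalog, a gold map table
#' whose equivalence categories match the designed fractions exactly, the
#' expected selected-term set, and bookkeeping sufficient to predict every
#' pipeline output.
#'
#' Planted terms use vocabulary exclusive to them, so after duplicate removal
#' and spell correction the corpus frequency of each planted term equals its
#' designed frequency exactly.
#'
#' @param design a [study_design()].
#' @return a `uit_synthetic_study` list: `corpus` (raw, pre-normalization),
#'   `lexicon_sources` (named list of word vectors for [build_lexicon()]),
#'   `lexicon`, `catalog_rf2` (RF2-shaped data frame), `catalog`
#'   (`uit_catalog`), `gold_map` (`uit_map_table`), `gold_selected`
#'   (character vector of expected selected candidate surfaces),
#'   `bookkeeping`.
#' @export
make_study <- function(design) {
  .assert(inherits(design, "uit_study_design"), "need a uit_study_design")
  .with_seed(design$seed, .make_study_impl(design))
}

.make_study_impl <- function(design) {
  dep <- design$departments
  n_terms <- design$n_terms

  # planted terms: language, gram length, designed Zipf frequency by rank
  lang <- ifelse(stats::runif(n_terms) < design$prop_thai, "thai", "english")
  gram <- sample(seq_along(design$ngram_weights), n_terms, replace = TRUE,
                 prob = design$ngram_weights)
  freq <- pmax(1L, as.integer(round(design$zipf_scale /
                                      seq_len(n_terms)^design$zipf_exponent)))

  # exclusive vocabulary per term + filler pools
  n_units_needed <- sum(gram[lang == "thai"])
  units <- .make_units(n_units_needed + 30L)
  filler_units <- utils::tail(units, 30L)
  term_units <- utils::head(units, n_units_needed)
  stop_pool <- default_stopwords()
  jarg <- .make_jargon(sum(gram[lang == "english"]) + 40L, reserved = stop_pool)
  filler_jargon <- utils::tail(jarg, 40L)
  term_jargon <- utils::head(jarg, length(jarg) - 40L)
  ui <- 0L
  ji <- 0L
  term_tokens <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    if (lang[i] == "thai") {
      term_tokens[[i]] <- term_units[ui + seq_len(gram[i])]
      ui <- ui + gram[i]
    } else {
      term_tokens[[i]] <- term_jargon[ji + seq_len(gram[i])]
      ji <- ji + gram[i]
    }
  }
  term_surface <- vapply(term_tokens, paste, character(1), collapse = " ")
  terms <- data.frame(surface = term_surface, language = lang, n = gram,
                      rank = seq_len(n_terms), designed_frequency = freq,
                      stringsAsFactors = FALSE)

  # abbreviations planted in raw (pre-normalization) text
  abbrevs <- character(0)
  while (length(abbrevs) < design$n_abbreviations) {
    a <- paste(sample(LETTERS, sample(3:4, 1), replace = TRUE), collapse = "")
    if (!(a %in% abbrevs)) abbrevs <- c(abbrevs, a)
  }

  # document skeleton
  doc_rows <- do.call(rbind, lapply(seq_len(nrow(dep)), function(d) {
    nd <- dep$n_documents[d]
    np <- dep$n_patients[d]
    pats <- sprintf("%s-P%03d", dep$department[d], seq_len(np))
    owner <- c(pats, sample(pats, max(0L, nd - np), replace = TRUE))[seq_len(nd)]
    data.frame(doc_id = sprintf("%s-D%04d", dep$department[d], seq_len(nd)),
               patient_id = owner, department = dep$department[d],
               target_len = pmax(12L, as.integer(round(
                 dep$words_per_doc[d] * stats::runif(nd, 0.6, 1.5)))),
               script_mix = dep$script_mix[d],
               stringsAsFactors = FALSE)
  }))
  # keep a patient's documents consecutive so "earlier document" is
  # well-defined in corpus order
  doc_rows <- doc_rows[order(match(doc_rows$department, dep$department),
                             doc_rows$patient_id), , drop = FALSE]
  rownames(doc_rows) <- NULL
  n_docs <- nrow(doc_rows)

  # occurrence placement: every planted occurrence lands in some document
  occ_term <- rep(seq_len(n_terms), times = freq)
  occ_abbr <- rep(seq_along(abbrevs) + n_terms,
                  times = rep(design$abbreviation_frequency, length(abbrevs)))
  occ <- sample(c(occ_term, occ_abbr))
  planted_tokens_total <- sum(freq * gram) +
    design$abbreviation_frequency * length(abbrevs)
  .assert(planted_tokens_total <= sum(doc_rows$target_len),
          paste("infeasible design: planted terms need %d tokens but the",
                "corpus holds only %d"),
          planted_tokens_total, sum(doc_rows$target_len))
  occ_doc <- sample(n_docs, length(occ), replace = TRUE,
                    prob = doc_rows$target_len)
  slot_token_list <- c(term_tokens, as.list(abbrevs))

  # realize documents: slots (occurrences + fillers) -> sentences -> text
  misspell_queue <- 0L # counted after assembly
  cc <- character(n_docs)
  pi_ <- character(n_docs)
  sent_keys <- new.env(parent = emptyenv()) # per-patient uniqueness
  all_sentences <- vector("list", n_docs)
  for (di in seq_len(n_docs)) {
    slots <- slot_token_list[occ[occ_doc == di]]
    n_planted <- sum(lengths(slots))
    n_fill <- max(3L, doc_rows$target_len[di] - n_planted)
    mix <- doc_rows$script_mix[di]
    fills <- lapply(seq_len(n_fill), function(k) {
      if (stats::runif(1) < mix) sample(filler_units, 1)
      else if (stats::runif(1) < design$stopword_filler_rate) sample(stop_pool, 1)
      else sample(filler_jargon, 1)
    })
    slots <- sample(c(slots, fills))
    # chunk slots into sentences of ~4-8 slots
    sents <- list()
    i <- 1L
    while (i <= length(slots)) {
      take <- min(length(slots) - i + 1L, sample(4:8, 1))
      sents[[length(sents) + 1L]] <- unlist(slots[i:(i + take - 1L)])
      i <- i + take
    }
    # realize each sentence, enforcing per-patient uniqueness of the
    # normalized form so duplicate elimination removes exactly the copies
    # injected below
    pid <- doc_rows$patient_id[di]
    txts <- character(length(sents))
    for (s in seq_along(sents)) {
      toks <- sents[[s]]
      repeat {
        txt <- .join_tokens(toks)
        if (stats::runif(1) < 0.3) txt <- paste0(txt, ".")
        key <- paste(pid, normalize_text(txt))
        if (is.null(sent_keys[[key]])) {
          assign(key, TRUE, envir = sent_keys)
          break
        }
        toks <- c(toks, sample(filler_jargon, 1))
      }
      txts[s] <- txt
    }
    all_sentences[[di]] <- txts
    cc[di] <- txts[1]
    pi_[di] <- paste(txts[-1], collapse = "\n")
  }

  # misspelling injection: corrupt eligible latin word instances in place
  n_miss <- 0L
  if (design$misspelling_rate > 0) {
    eligible_words <- c(term_jargon, filler_jargon)
    corrupt <- function(w) {
      p <- sample(nchar(w), 1)
      repeat {
        ch <- sample(letters, 1)
        if (ch != substr(w, p, p)) break
      }
      paste0(substr(w, 1, p - 1), ch, substr(w, p + 1, nchar(w)))
    }
    for (di in seq_len(n_docs)) {
      for (col in c("cc", "pi_")) {
        txt <- if (col == "cc") cc[di] else pi_[di]
        if (!nzchar(txt)) next
        words <- strsplit(txt, " ", fixed = TRUE)[[1]]
        elig <- which(sub("\\.$", "", words) %in% eligible_words)
        if (length(elig)) {
          hit <- elig[stats::runif(length(elig)) < design$misspelling_rate]
          for (h in hit) {
            dot <- grepl("\\.$", words[h])
            base <- sub("\\.$", "", words[h])
            words[h] <- paste0(corrupt(base), if (dot) "." else "")
            n_miss <- n_miss + 1L
          }
          txt <- paste(words, collapse = " ")
          if (col == "cc") cc[di] <- txt else pi_[di] <- txt
        }
      }
    }
  }

  # duplicate-sentence injection: copy raw sentences forward into later
  # documents of the same patient
  n_dup <- 0L
  dup_chars <- 0L
  if (design$duplicate_sentence_rate > 0) {
    for (pid in unique(doc_rows$patient_id)) {
      idx <- which(doc_rows$patient_id == pid)
      if (length(idx) < 2) next
      for (k in 2:length(idx)) {
        di <- idx[k]
        earlier <- unlist(lapply(idx[1:(k - 1)], function(e)
          strsplit(paste(cc[e], pi_[e], sep = "\n"), "\n")[[1]]))
        earlier <- earlier[nzchar(earlier)]
        own <- strsplit(paste(cc[di], pi_[di], sep = "\n"), "\n")[[1]]
        n_copy <- stats::rbinom(1, length(own), design$duplicate_sentence_rate)
        if (n_copy == 0) next
        copies <- sample(earlier, n_copy, replace = TRUE)
        pi_[di] <- paste(c(if (nzchar(pi_[di])) pi_[di], copies), collapse = "\n")
        n_dup <- n_dup + n_copy
        dup_chars <- dup_chars + sum(nchar(copies, type = "chars"))
      }
    }
  }

  corp <- corpus(doc_rows$doc_id, doc_rows$patient_id, doc_rows$department,
                 cc, pi_,
                 metadata = list(generator = "uitcoverage synthetic study",
                                 seed = design$seed))

  # lexicon sources: five word lists, as the real dictionary integrates them
  lexicon_sources <- list(
    wordnet_en = sort(c(stop_pool, filler_jargon)),
    wordnet_local = sort(c(term_units, filler_units)),
    concept_descriptions = sort(term_jargon),
    drug_db = sort(sample(filler_jargon, min(5L, length(filler_jargon)))),
    abbreviations = sort(abbrevs))
  lex <- build_lexicon(lexicon_sources)

  # gold map: categories allocated over entries by largest remainder
  gold <- .make_gold_map(design, terms)

  # catalog from the gold map's design; glosses kept >= 3 edits away from the
  # corpus vocabulary so they can never fake a lexical match
  cat_rf2 <- .make_catalog_rf2(gold$entries, gold$concepts,
                               reserved = c(stop_pool, jarg))
  catalog <- .catalog_from_rf2(cat_rf2)

  study <- list(design = design, corpus = corp,
                lexicon_sources = lexicon_sources, lexicon = lex,
                catalog_rf2 = cat_rf2, catalog = catalog,
                gold_map = gold$map,
                bookkeeping = list(
                  terms = gold$terms,
                  abbreviations = data.frame(
                    surface = abbrevs,
                    corpus_frequency = rep(design$abbreviation_frequency,
                                           length(abbrevs)),
                    stringsAsFactors = FALSE),
                  designed_equivalence_counts = gold$eq_counts,
                  designed_unmapped_counts = gold$unm_counts,
                  designed_direct_matches = gold$n_direct,
                  duplicates_injected = n_dup,
                  duplicate_chars_injected = dup_chars,
                  misspellings_injected = n_miss,
                  planted_tokens_total = planted_tokens_total,
                  filler_units = filler_units,
                  filler_jargon = filler_jargon))
  class(study) <- "uit_synthetic_study"
  study$gold_selected <- predict_pipeline_outputs(study)$selected
  study
}

# join a token sequence into raw text: adjacent continuous-script tokens are
# concatenated (continuous script has no spaces); any other boundary gets one
.join_tokens <- function(toks) {
  if (length(toks) == 1) return(toks)
  cont <- .has_continuous(toks)
  sep <- ifelse(cont[-length(toks)] & cont[-1], "", " ")
  paste0(paste0(toks[-length(toks)], sep, collapse = ""), toks[length(toks)])
}

#' @export
print.uit_synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<uit_synthetic_study> seed %d: %d documents, ",
                     "%d planted terms, %d map entries\n"),
              x$design$seed, nrow(x$corpus), nrow(x$bookkeeping$terms),
              nrow(x$gold_map)))
  invisible(x)
}

# ---- gold map + catalog ----------------------------------------------------

.make_gold_map <- function(design, terms) {
  n_terms <- nrow(terms)
  n_12many <- round(design$one_to_many_fraction * n_terms)
  n_entries <- n_terms + n_12many
  eq_counts <- .largest_remainder(design$equivalence_fractions, n_entries)
  unm_counts <- .largest_remainder(design$unmapped_fractions,
                                   eq_counts[["unmapped"]])

  # unmapped terms are single-entry terms; one-to-many terms are mapped
  ord <- sample(n_terms)
  unmapped_terms <- ord[seq_len(eq_counts[["unmapped"]])]
  rest <- setdiff(ord, unmapped_terms)
  many_terms <- rest[seq_len(n_12many)]

  entry_term <- c(setdiff(seq_len(n_terms), unmapped_terms), many_terms,
                  unmapped_terms)
  mapped_n <- length(entry_term) - length(unmapped_terms)
  cats <- sample(rep(c("full", "broader", "narrower", "inexact"),
                     times = eq_counts[c("full", "broader", "narrower",
                                         "inexact")]))
  equivalence <- c(cats, rep("unmapped", length(unmapped_terms)))
  unmapped_category <- c(rep(NA_character_, mapped_n),
                         sample(rep(.unmapped_categories, times = unm_counts)))

  # concepts: mostly fresh, a designed fraction reused
  concept_id <- rep(NA_character_, length(entry_term))
  next_id <- 900001L
  reuse_n <- round(design$concept_reuse_fraction * mapped_n)
  reuse_at <- if (reuse_n > 0) sample(seq_len(mapped_n)[-1],
                                      min(reuse_n, mapped_n - 1)) else integer(0)
  for (i in seq_len(mapped_n)) {
    if (i %in% reuse_at) {
      pool <- unique(concept_id[seq_len(i - 1)])
      concept_id[i] <- sample(pool, 1)
      # a one-to-many term must not map twice to the same concept
      tix <- entry_term[i]
      prev <- concept_id[seq_len(i - 1)][entry_term[seq_len(i - 1)] == tix]
      if (concept_id[i] %in% prev) {
        concept_id[i] <- as.character(next_id)
        next_id <- next_id + 1L
      }
    } else {
      concept_id[i] <- as.character(next_id)
      next_id <- next_id + 1L
    }
  }

  # direct lexical matches: Latin-term entries only
  mapped_lang <- terms$language[entry_term[seq_len(mapped_n)]]
  n_direct_want <- round(design$direct_match_fraction * n_entries)
  eng_idx <- which(mapped_lang == "english")
  direct_at <- sample(eng_idx, min(n_direct_want, length(eng_idx)))
  direct <- rep(FALSE, length(entry_term))
  direct[direct_at] <- TRUE

  map <- map_table(data.frame(
    source_term = terms$surface[entry_term],
    source_language = terms$language[entry_term],
    n = terms$n[entry_term],
    target_concept_id = concept_id,
    equivalence = equivalence,
    unmapped_category = unmapped_category,
    stringsAsFactors = FALSE))

  term_book <- terms
  term_book$mapped <- !(seq_len(n_terms) %in% unmapped_terms)
  term_book$one_to_many <- seq_len(n_terms) %in% many_terms

  list(map = map, terms = term_book,
       eq_counts = eq_counts, unm_counts = unm_counts,
       n_direct = sum(direct),
       entries = data.frame(source_term = terms$surface[entry_term],
                            language = terms$language[entry_term],
                            concept_id = concept_id,
                            equivalence = equivalence,
                            direct = direct,
                            stringsAsFactors = FALSE),
       concepts = unique(stats::na.omit(concept_id)))
}

# RF2-style description rows for the designed catalog: one FSN per concept,
# one synonym per mapped entry (word-multiset-equal to the source term when
# the entry is a designed direct lexical match)
.make_catalog_rf2 <- function(entries, concept_ids, reserved = character(0)) {
  gloss_pool <- .make_jargon(length(concept_ids) + 4L, reserved = reserved)
  extra <- utils::tail(gloss_pool, 4L)
  gloss <- utils::head(gloss_pool, length(concept_ids))
  names(gloss) <- concept_ids
  rows <- list()
  did <- 710000L
  add <- function(cid, term, type) {
    did <<- did + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.character(did), effectiveTime = "20240101", active = "1",
      moduleId = "900000000000207008", conceptId = cid, languageCode = "en",
      typeId = if (type == "fsn") .FSN_TYPE else .SYN_TYPE,
      term = term, caseSignificanceId = "900000000000448009",
      stringsAsFactors = FALSE)
  }
  for (cid in concept_ids) add(cid, sprintf("%s (finding)", gloss[cid]), "fsn")
  mapped <- entries[entries$equivalence != "unmapped", , drop = FALSE]
  for (i in seq_len(nrow(mapped))) {
    cid <- mapped$concept_id[i]
    if (mapped$direct[i]) {
      words <- strsplit(mapped$source_term[i], " ", fixed = TRUE)[[1]]
      add(cid, paste(rev(words), collapse = " "), "synonym")
    } else if (mapped$language[i] == "english") {
      # supersets never bag-match the term itself
      add(cid, paste(mapped$source_term[i], extra[1]), "synonym")
    } else {
      add(cid, paste(gloss[cid], extra[2]), "synonym")
    }
  }
  # an inactive distractor row, exercised by the loader's report
  r <- rows[[1]]
  r$id <- "709999"
  r$active <- "0"
  r$term <- paste(extra[3], extra[4])
  r$typeId <- .SYN_TYPE
  rows[[length(rows) + 1L]] <- r
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- reference segmenter + prediction oracle -------------------------------

#' Brute-force reference segmenter
#'
#' An independently written longest-match-first segmenter used as the test
#' oracle for [max_match_tokenize()]: at each position it compares the
#' remaining string against every dictionary surface by prefix test and takes
#' the longest match, recursing on the rest; unmatched characters merge into
#' runs bounded by whitespace, script change, or the next matchable position.
#' No index structures are shared with the production tokenizer.
#'
#' @param text a single normalized string.
#' @param surfaces character vector of dictionary match keys.
#' @param allow_multiword allow surfaces containing spaces to match.
#' @return character vector of token surfaces in order.
#' @export
reference_segment <- function(text, surfaces, allow_multiword = TRUE) {
  if (!allow_multiword) surfaces <- surfaces[!grepl(" ", surfaces, fixed = TRUE)]
  out <- character(0)
  s <- text
  best_prefix <- function(s) {
    hit <- surfaces[startsWith(s, surfaces)]
    if (length(hit) == 0) return(NULL)
    hit[which.max(nchar(hit, type = "chars"))]
  }
  while (nchar(s, type = "chars") > 0) {
    ch <- substr(s, 1, 1)
    if (grepl("^\\s", ch)) {
      s <- substring(s, 2)
      next
    }
    m <- best_prefix(s)
    if (!is.null(m)) {
      out <- c(out, m)
      s <- substring(s, nchar(m, type = "chars") + 1L)
    } else {
      cls0 <- .char_class(utf8ToInt(ch))
      run <- ch
      s <- substring(s, 2)
      while (nchar(s, type = "chars") > 0) {
        nx <- substr(s, 1, 1)
        if (grepl("^\\s", nx)) break
        if (.char_class(utf8ToInt(nx)) != cls0) break
        if (!is.null(best_prefix(s))) break
        run <- paste0(run, nx)
        s <- substring(s, 2)
      }
      out <- c(out, run)
    }
  }
  out
}

#' Predict pipeline outputs from a synthetic study
#'
#' The test oracle for the end-to-end pipeline: preprocesses the study corpus
#' with the standard steps (normalize, per-patient duplicate elimination,
#' spell check), then recomputes, by independent brute force, the
#' segmentation ([reference_segment()]), the N-gram frequencies (direct
#' window enumeration with [table()]), the selection set (direct application
#' of the selection predicate) and the gold-map coverage counts.
#'
#' @param study a `uit_synthetic_study`.
#' @param config a [selection_config()].
#' @return list: `candidates` (surface, n, frequency), `selected` (surfaces
#'   expected selected), `coverage` (designed counts and percentages from the
#'   gold map), `duplicates_removed_expected`, `corrections_expected`.
#' @export
predict_pipeline_outputs <- function(study, config = selection_config()) {
  corp <- normalize_corpus(study$corpus)
  dd <- dedup_sentences(corp)
  sc <- apply_spell_check(dd$corpus, study$lexicon)
  corp <- sc$corpus
  keys <- study$lexicon$entries$key

  chunks <- list()
  for (i in seq_len(nrow(corp))) {
    for (txt in c(corp$chief_complaint[i], corp$present_illness[i])) {
      for (line in strsplit(txt, "\n", fixed = TRUE)[[1]]) {
        if (!nzchar(line)) next
        toks <- reference_segment(line, keys)
        L <- length(toks)
        for (n in seq_len(min(config$n_max, L))) {
          chunks[[length(chunks) + 1L]] <-
            vapply(seq_len(L - n + 1L), function(s)
              paste(toks[s:(s + n - 1L)], collapse = " "), character(1))
        }
      }
    }
  }
  tab <- table(unlist(chunks, use.names = FALSE))
  cand <- data.frame(surface = names(tab), frequency = as.integer(tab),
                     stringsAsFactors = FALSE)
  cand$n <- lengths(strsplit(cand$surface, " ", fixed = TRUE))

  # selection predicate, applied directly
  tokl <- strsplit(cand$surface, " ", fixed = TRUE)
  stopish <- vapply(tokl, function(tt) mean(.is_stopish(tt, config)), numeric(1))
  edge_bad <- vapply(tokl, function(tt) {
    e <- tolower(c(tt[1], tt[length(tt)]))
    any(e %in% config$stopwords) || any(e %in% config$prepositions)
  }, logical(1))
  keep <- stopish <= config$stopword_fraction_max & !edge_bad
  sel <- logical(nrow(cand))
  for (n in unique(cand$n)) {
    idx <- which(cand$n == n & keep)
    o <- order(-cand$frequency[idx], cand$surface[idx], method = "radix")
    pctile <- numeric(length(idx))
    pctile[o] <- 100 * seq_along(idx) / length(idx)
    sel[idx] <- pctile <= config$percentile_cut |
      cand$frequency[idx] >= config$frequency_cut
  }

  eqc <- table(factor(study$gold_map$equivalence, .equivalences))
  list(candidates = cand[order(cand$n, -cand$frequency, cand$surface), ],
       selected = sort(cand$surface[sel]),
       coverage = list(
         counts = as.integer(eqc),
         equivalence = names(eqc),
         full_pct = .pct(eqc[["full"]], nrow(study$gold_map)),
         unmapped_pct = .pct(eqc[["unmapped"]], nrow(study$gold_map))),
       duplicates_removed_expected = study$bookkeeping$duplicates_injected,
       corrections_expected = study$bookkeeping$misspellings_injected)
}

#' Write a synthetic study to disk
#'
#' Writes the corpus (line-delimited records), the five word-list sources,
#' the RF2-style catalog snapshot, the gold map table and a bookkeeping
#' manifest. Byte-identical for identical design and seed.
#'
#' @param study a `uit_synthetic_study`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "lexicon"), showWarnings = FALSE)
  write_corpus(study$corpus, file.path(dir, "corpus.tsv"))
  for (tag in names(study$lexicon_sources)) {
    con <- file(file.path(dir, "lexicon", paste0(tag, ".txt")), open = "wb")
    writeLines(enc2utf8(study$lexicon_sources[[tag]]), con, useBytes = TRUE)
    close(con)
  }
  utils::write.table(study$catalog_rf2, file.path(dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_map_table(study$gold_map, file.path(dir, "gold_map.tsv"))
  utils::write.table(study$bookkeeping$terms, file.path(dir, "terms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  con <- file(file.path(dir, "manifest.txt"), open = "wb")
  writeLines(enc2utf8(c(
    sprintf("seed: %d", study$design$seed),
    sprintf("documents: %d", nrow(study$corpus)),
    sprintf("planted_terms: %d", nrow(study$bookkeeping$terms)),
    sprintf("map_entries: %d", nrow(study$gold_map)),
    sprintf("duplicates_injected: %d", study$bookkeeping$duplicates_injected),
    sprintf("misspellings_injected: %d", study$bookkeeping$misspellings_injected)
  )), con, useBytes = TRUE)
  close(con)
  invisible(dir)
}
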