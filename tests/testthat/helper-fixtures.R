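# Shared fixtures, built in code.

# map table with the benchmark equivalence x language entry counts
benchmark_map_counts <- function() {
  data.frame(
    equivalence = rep(c("full", "broader", "narrower", "inexact", "unmapped"),
                      each = 2),
    language = rep(c("english", "thai"), times = 5),
    n = c(973, 808, 65, 58, 38, 18, 37, 44, 27, 15),
    stringsAsFactors = FALSE)
}

# build a map table realizing given category/language entry counts; the
# entry total is preserved while `one_to_many_sizes` (e.g. c(rep(2, 27), 3))
# regroups that many leading mapped entries under shared source terms, and
# `n_unique_concepts` collapses target ids to a designed distinct count
counts_map_table <- function(counts = benchmark_map_counts(),
                             one_to_many_sizes = integer(0),
                             n_unique_concepts = NULL) {
  rows <- list()
  tid <- 0L
  for (i in seq_len(nrow(counts))) {
    k <- counts$n[i]
    if (k == 0) next
    term <- sprintf("%s-%s-%04d", counts$equivalence[i], counts$language[i],
                    tid + seq_len(k))
    if (counts$language[i] == "thai") term <- paste0("ก", term)
    tid <- tid + k
    rows[[i]] <- data.frame(
      source_term = term,
      source_language = counts$language[i],
      target_concept_id = if (counts$equivalence[i] == "unmapped")
        NA_character_ else sprintf("c%05d", tid + seq_len(k)),
      equivalence = counts$equivalence[i],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (!is.null(n_unique_concepts)) {
    mapped <- which(df$equivalence != "unmapped")
    n_mapped <- length(mapped)
    stopifnot(n_unique_concepts <= n_mapped)
    ids <- sprintf("u%05d", seq_len(n_unique_concepts))
    df$target_concept_id[mapped] <-
      ids[c(seq_len(n_unique_concepts),
            rep(1L, n_mapped - n_unique_concepts))]
  }
  if (length(one_to_many_sizes)) {
    mapped <- which(df$equivalence != "unmapped")
    stopifnot(sum(one_to_many_sizes) <= length(mapped))
    grp <- rep(seq_along(one_to_many_sizes), times = one_to_many_sizes)
    df$source_term[mapped[seq_along(grp)]] <- sprintf("many-term-%03d", grp)
  }
  map_table(df)
}

# random but internally consistent map table, for recount-oracle tests
random_map_table <- function(n_terms = 60, seed = 1) {
  set.seed(seed)
  eq <- sample(c("full", "broader", "narrower", "inexact", "unmapped"),
               n_terms, replace = TRUE, prob = c(.6, .1, .1, .1, .1))
  lang <- sample(c("english", "thai"), n_terms, replace = TRUE)
  term <- sprintf("term%03d", seq_len(n_terms))
  term[lang == "thai"] <- paste0("ข", term[lang == "thai"])
  rows <- lapply(seq_len(n_terms), function(i) {
    if (eq[i] == "unmapped") {
      data.frame(source_term = term[i], source_language = lang[i],
                 target_concept_id = NA_character_, equivalence = "unmapped",
                 unmapped_category = sample(c("ambiguous", "multiconcept",
                                              "no_concept"), 1),
                 stringsAsFactors = FALSE)
    } else {
      k <- sample(c(1, 1, 1, 2), 1) # occasional one-to-many
      data.frame(source_term = term[i], source_language = lang[i],
                 target_concept_id = sprintf("c%03d", sample(200, k)),
                 equivalence = eq[i], unmapped_category = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  map_table(do.call(rbind, rows))
}

# small raw corpus with hand-placed content
tiny_corpus <- function() {
  corpus(doc_id = c("d1", "d2", "d3"),
         patient_id = c("p1", "p1", "p2"),
         department = c("FM", "FM", "ER"),
         chief_complaint = c("Chest Pain", "follow up", "fever"),
         present_illness = c("pain for 2 days", "pain for 2 days",
                             "high fever tonight"))
}

# random (lexicon, string) case for tokenizer equivalence testing
random_segmentation_case <- function() {
  alphabet <- c(letters[1:4], intToUtf8(0xE000 + 0:3, multiple = TRUE))
  n_entries <- sample(1:30, 1)
  entries <- unique(vapply(seq_len(n_entries), function(i)
    paste(sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = ""),
    character(1)))
  len <- sample(0:40, 1)
  chars <- sample(c(alphabet, " "), len, replace = TRUE)
  list(entries = entries, text = trimws(paste(chars, collapse = "")))
}
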