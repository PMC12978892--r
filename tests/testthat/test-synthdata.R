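# a desk-scale design: same structure as the default, shrunk for unit tests
tiny_design <- function(seed = 1L, ...) {
  study_design(
    seed = seed,
    departments = data.frame(
      department = c("FM", "ER", "IM"),
      n_patients = c(3L, 4L, 6L),
      n_documents = c(6L, 6L, 12L),
      script_mix = c(0.59, 0.637, 0.397),
      words_per_doc = c(60, 74, 107),
      stringsAsFactors = FALSE),
    n_terms = 30L,
    zipf_scale = 120,
    ...)
}

test_that("identical seed and design give identical studies, bit-for-bit on disk", {
  s1 <- make_study(tiny_design(seed = 5))
  s2 <- make_study(tiny_design(seed = 5))
  expect_identical(s1$corpus$chief_complaint, s2$corpus$chief_complaint)
  expect_identical(s1$corpus$present_illness, s2$corpus$present_illness)
  expect_identical(as.data.frame(s1$gold_map), as.data.frame(s2$gold_map))
  expect_identical(s1$gold_selected, s2$gold_selected)
  d1 <- tempfile("study1")
  d2 <- tempfile("study2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_study(s1, d1)
  write_study(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  # a different seed gives a different corpus
  s3 <- make_study(tiny_design(seed = 6))
  expect_false(identical(s1$corpus$present_illness, s3$corpus$present_illness))
})

test_that("a single noise-free planted unigram is harvested at exactly its designed frequency", {
  des <- study_design(
    seed = 4,
    departments = data.frame(department = "FM", n_patients = 1L,
                             n_documents = 1L, script_mix = 0,
                             words_per_doc = 20, stringsAsFactors = FALSE),
    n_terms = 1L, prop_thai = 0, ngram_weights = c(1, 0, 0, 0, 0),
    zipf_scale = 5, one_to_many_fraction = 0,
    duplicate_sentence_rate = 0, misspelling_rate = 0, n_abbreviations = 0L)
  st <- make_study(des)
  term <- st$bookkeeping$terms$surface
  expect_identical(st$bookkeeping$terms$designed_frequency, 5L)
  res <- run_uit_pipeline(st$corpus, st$lexicon)
  expect_identical(res$candidates$frequency[res$candidates$surface == term], 5L)
  expect_identical(res$dedup_report$duplicates_removed, 0L)
  expect_identical(res$spell_report$corrections_applied, 0L)
})

test_that("infeasible designs (planted tokens exceed corpus capacity) error out", {
  des <- study_design(
    seed = 1,
    departments = data.frame(department = "FM", n_patients = 1L,
                             n_documents = 1L, script_mix = 0,
                             words_per_doc = 12, stringsAsFactors = FALSE),
    n_terms = 5L, zipf_scale = 1000, n_abbreviations = 0L)
  expect_error(make_study(des), "infeasible design")
})

test_that("gold-map categories realize the designed fractions by largest remainder", {
  fr <- c(full = 0.855, broader = 0.059, narrower = 0.027, inexact = 0.039,
          unmapped = 0.020)
  alloc <- uitcoverage:::.largest_remainder(fr, 1000L)
  expect_identical(unname(alloc), c(855L, 59L, 27L, 39L, 20L))
  expect_equal(unname(round_half_up(100 * alloc / 1000, 2)),
               c(85.50, 5.90, 2.70, 3.90, 2.00))

  st <- make_study(tiny_design(seed = 3))
  cov <- concept_coverage(st$gold_map)
  designed <- st$bookkeeping$designed_equivalence_counts
  expect_equal(setNames(cov$by_equivalence$total, cov$by_equivalence$equivalence),
               designed[cov$by_equivalence$equivalence],
               ignore_attr = FALSE)
})

test_that("with zero noise the pipeline recovers the gold selection and frequencies exactly", {
  st <- make_study(tiny_design(seed = 2, duplicate_sentence_rate = 0,
                               misspelling_rate = 0))
  res <- run_uit_pipeline(st$corpus, st$lexicon)
  sel <- sort(res$candidates$surface[res$candidates$selected])
  expect_identical(sel, st$gold_selected)
  m <- match(st$bookkeeping$terms$surface, res$candidates$surface)
  expect_false(anyNA(m))
  expect_identical(res$candidates$frequency[m],
                   st$bookkeeping$terms$designed_frequency)
  # without copied-forward sentences, abbreviations appear in the raw text at
  # exactly their planted frequency
  ab <- res$abbreviation_candidates[order(res$abbreviation_candidates$surface), ]
  book <- st$bookkeeping$abbreviations[order(st$bookkeeping$abbreviations$surface), ]
  expect_identical(ab$surface, book$surface)
  expect_identical(ab$corpus_frequency, book$corpus_frequency)
})

test_that("injected noise is removed exactly: duplicates and misspellings", {
  st <- make_study(tiny_design(seed = 9, duplicate_sentence_rate = 0.3,
                               misspelling_rate = 0.02))
  expect_gt(st$bookkeeping$duplicates_injected, 0L)
  expect_gt(st$bookkeeping$misspellings_injected, 0L)
  res <- run_uit_pipeline(st$corpus, st$lexicon)
  expect_identical(res$dedup_report$duplicates_removed,
                   st$bookkeeping$duplicates_injected)
  expect_identical(res$spell_report$corrections_applied,
                   st$bookkeeping$misspellings_injected)
  # planted frequencies survive the noise exactly (exclusive vocabulary)
  m <- match(st$bookkeeping$terms$surface, res$candidates$surface)
  expect_identical(res$candidates$frequency[m],
                   st$bookkeeping$terms$designed_frequency)
  # copied-forward sentences may repeat abbreviations, so the raw harvest sees
  # at least the planted frequency, never less, and nothing spurious
  ab <- res$abbreviation_candidates[order(res$abbreviation_candidates$surface), ]
  book <- st$bookkeeping$abbreviations[order(st$bookkeeping$abbreviations$surface), ]
  expect_identical(ab$surface, book$surface)
  expect_true(all(ab$corpus_frequency >= book$corpus_frequency))
})

test_that("study artifacts round-trip from disk", {
  st <- make_study(tiny_design(seed = 8))
  d <- tempfile("study")
  on.exit(unlink(d, recursive = TRUE))
  write_study(st, d)
  corp <- read_corpus(file.path(d, "corpus.tsv"))
  expect_identical(corp$present_illness, st$corpus$present_illness)
  gm <- load_map_table(file.path(d, "gold_map.tsv"))
  expect_identical(gm$equivalence, st$gold_map$equivalence)
  expect_identical(gm$target_concept_id, st$gold_map$target_concept_id)
  cat_ <- load_concept_catalog(file.path(d, "catalog.tsv"))
  expect_identical(sort(cat_$concepts$concept_id),
                   sort(unique(st$gold_map$target_concept_id[
                     st$gold_map$equivalence != "unmapped"])))
  expect_identical(cat_$load_report$rows_inactive_dropped, 1L)
  lex <- build_lexicon(list(
    wordnet_en = file.path(d, "lexicon", "wordnet_en.txt"),
    wordnet_local = file.path(d, "lexicon", "wordnet_local.txt"),
    concept_descriptions = file.path(d, "lexicon", "concept_descriptions.txt"),
    drug_db = file.path(d, "lexicon", "drug_db.txt"),
    abbreviations = file.path(d, "lexicon", "abbreviations.txt")))
  expect_identical(sort(lex$entries$key), sort(st$lexicon$entries$key))
})
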