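# a small RF2-shaped description snapshot written to disk
write_demo_rf2 <- function(path) {
  fsn <- "900000000000003001"
  syn <- "900000000000013009"
  df <- data.frame(
    id = as.character(1:6),
    effectiveTime = "20240101", active = c("1", "1", "1", "1", "0", "1"),
    moduleId = "m", conceptId = c("101", "101", "101", "102", "102", "102"),
    languageCode = "en",
    typeId = c(fsn, syn, syn, fsn, syn, syn),
    term = c("Dressing of wound (procedure)", "Dressing wound",
             "Wound care", "Follow-up visit (procedure)",
             "retired synonym", "Follow-up encounter"),
    caseSignificanceId = "cs", stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

test_that("RF2 snapshots load into concepts and descriptions, dropping inactive rows", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  cat_ <- load_concept_catalog(write_demo_rf2(p))
  expect_identical(sort(cat_$concepts$concept_id), c("101", "102"))
  expect_identical(cat_$concepts$semantic_tag, c("procedure", "procedure"))
  expect_identical(nrow(cat_$descriptions), 5L)
  expect_identical(cat_$load_report$rows_read, 6L)
  expect_identical(cat_$load_report$rows_inactive_dropped, 1L)
  expect_identical(sum(cat_$descriptions$type == "fsn"), 2L)
})

test_that("direct lexical matching is a case- and order-insensitive bag-of-words test", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  cat_ <- load_concept_catalog(write_demo_rf2(p))
  hit <- detect_direct_lexical_match(
    c("wound dressing", "Wound-Dressing", "wound care", "f u",
      "follow up visit", "retired synonym"), cat_)
  expect_identical(hit$direct_match, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # hyphenation is punctuation, stripped before comparison; inactive
  # descriptions never match; paraphrases and abbreviations never match
})

test_that("term language comes from the script, mixed defaulting to the continuous language", {
  u <- intToUtf8(0xE001)
  expect_identical(classify_term_language(c("wound", u, paste0("x", u), "2 days")),
                   c("english", "thai", "thai", "english"))
})

test_that("map tables enforce the mapped/unmapped invariants", {
  expect_error(map_table(data.frame(source_term = "t", target_concept_id = "1",
                                    equivalence = "sorta")), "unknown equivalence")
  expect_error(map_table(data.frame(source_term = "t",
                                    target_concept_id = "1",
                                    equivalence = "unmapped")),
               "unmapped entries must have no target")
  expect_error(map_table(data.frame(source_term = "t",
                                    target_concept_id = NA_character_,
                                    equivalence = "full")),
               "mapped entries must carry a target")
  expect_error(map_table(data.frame(source_term = c("t", "t"),
                                    target_concept_id = c("1", NA),
                                    equivalence = c("full", "unmapped"))),
               "both mapped and unmapped")
  expect_error(map_table(data.frame(source_term = "t", target_concept_id = "1",
                                    equivalence = "full",
                                    unmapped_category = "ambiguous")),
               "unmapped_category may only be set")
})

test_that("entry accounting is recomputed correctly on arbitrary tables", {
  m <- random_map_table(n_terms = 80, seed = 7)
  acc <- attr(m, "accounting")
  # independent recount
  unm <- m$equivalence == "unmapped"
  counts <- table(m$source_term[!unm])
  expect_identical(acc$n_entries, nrow(m))
  expect_identical(acc$n_one_to_one_terms, sum(counts == 1))
  expect_identical(acc$n_one_to_many_terms, sum(counts > 1))
  expect_identical(acc$n_one_to_many_pairs, as.integer(sum(counts[counts > 1])))
  expect_identical(acc$n_unmapped, sum(unm))
  expect_identical(acc$n_unique_concepts,
                   length(unique(m$target_concept_id[!unm])))
  expect_identical(acc$n_one_to_one_terms + acc$n_one_to_many_pairs +
                     acc$n_unmapped, acc$n_entries)
})

test_that("map-table files round-trip through the relationship vocabulary", {
  m <- random_map_table(n_terms = 40, seed = 3)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_map_table(m, p)
  raw <- utils::read.delim(p, stringsAsFactors = FALSE, colClasses = "character")
  expect_true(all(raw$relationship[raw$status == "MAPPED"] %in%
                    c("TARGET_EQUIVALENT", "TARGET_BROADER",
                      "TARGET_NARROWER", "TARGET_INEXACT")))
  m2 <- load_map_table(p)
  for (col in c("source_term", "source_language", "equivalence",
                "target_concept_id", "unmapped_category")) {
    expect_identical(m2[[col]], m[[col]])
  }
  expect_identical(m2$n, as.integer(m$n))
})
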