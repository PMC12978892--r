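test_that("corpus constructor enforces its invariants", {
  x <- tiny_corpus()
  expect_s3_class(x, "uit_corpus")
  expect_identical(nrow(x), 3L)

  expect_error(corpus(c("d1", "d1"), c("p1", "p2"), c("FM", "FM"),
                      c("a", "b"), c("", "")), "duplicate doc_id")
  expect_error(corpus("d1", "p1", "XX", "a", ""), "unknown department")
  expect_error(corpus("d1", "p1", "FM", "", "  "), "both text sections empty")
  # but downstream steps may legitimately empty a document
  emptyish <- tiny_corpus()
  emptyish$present_illness[1] <- ""
  emptyish$chief_complaint[1] <- ""
  expect_error(validate_corpus(emptyish), "both text sections empty")
  expect_silent(validate_corpus(emptyish, allow_empty = TRUE))
})

test_that("corpus files round-trip, including embedded tabs, newlines and backslashes", {
  x <- corpus(
    doc_id = c("d1", "d2"),
    patient_id = c("p1", "p2"),
    department = c("FM", "IM"),
    chief_complaint = c("line one\nline two", "has\ttab and back\\slash"),
    present_illness = c("", "trailing empty field test"))
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_corpus(x, p)
  y <- read_corpus(p)
  expect_identical(y$chief_complaint, x$chief_complaint)
  expect_identical(y$present_illness, x$present_illness)
  expect_identical(y$doc_id, x$doc_id)
  expect_identical(attr(y, "metadata")$n_excluded, 0L)
})

test_that("reading excludes records whose both sections are empty and counts them", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  con <- file(p, "wb")
  writeLines(c("doc_id\tpatient_id\tdepartment\tchief_complaint\tpresent_illness",
               "d1\tp1\tFM\tchest pain\t",
               "d2\tp1\tFM\t\t",
               "d3\tp2\tER\t\tfever"), con)
  close(con)
  x <- read_corpus(p)
  expect_identical(x$doc_id, c("d1", "d3"))
  expect_identical(attr(x, "metadata")$n_excluded, 1L)
})

test_that("department summary appends a total row and both share percentages", {
  s <- department_summary(data.frame(
    department = c("FM", "ER", "IM"),
    n_documents = c(10L, 20L, 70L),
    total_words = c(100L, 300L, 600L),
    total_continuous_words = c(50L, 100L, 150L)))
  expect_identical(s$department, c("FM", "ER", "IM", "Total"))
  expect_identical(s$n_documents[4], 100L)
  expect_equal(s$continuous_word_pct,
               round_half_up(c(50, 100 * 100 / 300, 25, 30), 2))
  expect_equal(s$document_share_pct, c(10, 20, 70, 100))
})

test_that("corpus statistics count words, continuous words and per-patient documents", {
  x <- corpus(doc_id = c("d1", "d2", "d3"),
              patient_id = c("p1", "p1", "p2"),
              department = c("FM", "FM", "ER"),
              chief_complaint = c("a", "b", "c"),
              present_illness = c("", "", ""))
  pua <- intToUtf8(0xE001)
  toks <- list(c("pain", pua, pua), c("pain", "fever"), c(pua))
  st <- compute_corpus_stats(x, toks)
  fm <- st[st$department == "FM", ]
  expect_identical(fm$n_patients, 1L)
  expect_identical(fm$n_documents, 2L)
  expect_identical(fm$total_words, 5L)
  expect_identical(fm$total_continuous_words, 2L)
  expect_equal(fm$total_continuous_pct, 40)
  expect_identical(fm$unique_words, 3L)   # pain, pua, fever
  expect_identical(fm$unique_continuous_words, 1L)
  tot <- st[st$department == "Total", ]
  expect_identical(tot$n_patients, 2L)
  expect_identical(attr(st, "n_patients_by_department_sum"), 2L)
  # words per doc over FM docs: lengths 3 and 2 -> median 2.5
  expect_equal(fm$words_per_doc_median, 2.5)
})

test_that("patients attending several departments are counted once in the total row", {
  x <- corpus(doc_id = c("d1", "d2"),
              patient_id = c("p1", "p1"),
              department = c("FM", "ER"),
              chief_complaint = c("a", "b"),
              present_illness = c("", ""))
  st <- compute_corpus_stats(x, list("a", "b"))
  expect_identical(st$n_patients[st$department == "Total"], 1L)
  expect_identical(attr(st, "n_patients_by_department_sum"), 2L)
})
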