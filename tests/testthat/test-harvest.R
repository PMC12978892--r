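test_that("N-gram windows are counted within sentences only", {
  cand <- generate_ngrams(list(c("a", "b", "a", "b")), n_max = 2)
  got <- setNames(cand$frequency, cand$surface)
  expect_identical(got[["a"]], 2L)
  expect_identical(got[["b"]], 2L)
  expect_identical(got[["a b"]], 2L)
  expect_identical(got[["b a"]], 1L)

  # no window spans a sentence (or section) boundary
  doc <- data.frame(surface = c("a", "b", "c", "d"),
                    section = c("cc", "cc", "pi", "pi"),
                    sentence = c(1L, 1L, 1L, 2L))
  cand2 <- generate_ngrams(list(doc), n_max = 2)
  expect_true("a b" %in% cand2$surface)
  expect_false(any(c("b c", "c d") %in% cand2$surface))
})

test_that("syntactic filters apply with the documented precedence", {
  cand <- generate_ngrams(list(c("of", "the", "pain", "of", "pain",
                                 "the", "pain", "2")), n_max = 3)
  cand <- filter_candidates(cand)
  reason <- setNames(cand$filtered_reason, cand$surface)
  expect_identical(reason[["of the"]], "stopword_fraction")    # 2/2 stopish
  expect_identical(reason[["pain of"]], "boundary_preposition")
  expect_identical(reason[["the pain"]], "boundary_stopword")
  expect_identical(reason[["2"]], "stopword_fraction")         # pure number
  expect_true(is.na(reason[["pain"]]))
  expect_true(is.na(reason[["pain 2"]]))                       # 1/2 stopish, not > 0.5
  # a filtered candidate can never be selected
  sel <- select_terms(rank_candidates(cand))
  expect_false(any(sel$selected & !is.na(sel$filtered_reason)))
})

test_that("ranking is frequency-descending with lexicographic ties and linear percentiles", {
  cand <- generate_ngrams(list(rep(c("zebra", "apple"), 5), "mango"))
  cand <- rank_candidates(filter_candidates(cand))
  r <- setNames(cand$rank_within_n, cand$surface)
  expect_identical(r[["apple"]], 1L)  # ties at 5 break lexicographically
  expect_identical(r[["zebra"]], 2L)
  expect_identical(r[["mango"]], 3L)
  p <- setNames(cand$percentile_within_n, cand$surface)
  expect_equal(unname(p[c("apple", "zebra", "mango")]),
               100 * (1:3) / 3)
})

test_that("selection takes unfiltered candidates in the top percentile or above the frequency cut", {
  cand <- data.frame(surface = c("alpha", "beta", "gamma", "delta", "of"),
                     n = 1L,
                     frequency = c(500L, 50L, 5L, 4L, 900L),
                     filtered_reason = NA_character_,
                     rank_within_n = NA_integer_,
                     percentile_within_n = NA_real_,
                     selected = FALSE, review_status = "pending",
                     stringsAsFactors = FALSE)
  class(cand) <- c("uit_candidates", "data.frame")
  cfg <- selection_config(percentile_cut = 50, frequency_cut = 300)
  out <- select_terms(rank_candidates(filter_candidates(cand, cfg)), cfg)
  sel <- setNames(out$selected, out$surface)
  expect_true(sel[["alpha"]])    # rank 1/4 = 25% and frequency >= 300
  expect_true(sel[["beta"]])     # rank 2/4 = 50% exactly (inclusive cut)
  expect_false(sel[["gamma"]])   # 75%, frequency below the cut
  expect_false(sel[["delta"]])
  expect_false(sel[["of"]])      # filtered despite its frequency
})

test_that("review sheets round-trip and reject decisions for unknown candidates", {
  cand <- select_terms(rank_candidates(filter_candidates(
    generate_ngrams(list(c("alpha", "beta", "alpha"))))))
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  export_review_sheet(cand, p)
  sheet <- utils::read.delim(p, stringsAsFactors = FALSE, na.strings = "")
  sheet$review_status <- c("accepted", "rejected")[match(sheet$surface,
                                                         c("alpha", "beta"))]
  utils::write.table(sheet, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  out <- import_review_decisions(cand, p)
  expect_identical(setNames(out$review_status, out$surface)[["alpha"]], "accepted")
  expect_identical(final_terms(out)$surface, "alpha")

  bad <- sheet
  bad$surface[1] <- "never-seen"
  utils::write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_error(import_review_decisions(cand, p), "unknown candidate")
})
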