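test_that("half-up rounding differs from banker's rounding exactly on the half cases", {
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(2.02, 2), 2.02)
  expect_equal(round_half_up(c(1.005, 1.015, 1.025), 2), c(1.01, 1.02, 1.03))
})

test_that("coverage percentages are recounted from any map table with the entry denominator", {
  m <- random_map_table(n_terms = 70, seed = 11)
  cov <- concept_coverage(m)
  n <- nrow(m)
  expect_identical(cov$n_entries, n)
  for (eq in c("full", "broader", "narrower", "inexact", "unmapped")) {
    row <- cov$by_equivalence[cov$by_equivalence$equivalence == eq, ]
    expect_equal(row$total, sum(m$equivalence == eq))
    expect_identical(row$english, sum(m$equivalence == eq &
                                        m$source_language == "english"))
    expect_equal(row$total_pct, round_half_up(100 * row$total / n, 2))
  }
  expect_equal(cov$concept_coverage_full_pct,
               round_half_up(100 * sum(m$equivalence == "full") / n, 2))
  expect_equal(cov$concept_coverage_full_plus_partial_pct,
               round_half_up(100 * sum(m$equivalence != "unmapped") / n, 2))
  expect_equal(cov$unmapped_pct + cov$concept_coverage_full_plus_partial_pct,
               100, tolerance = 0.011) # the two rounded halves can differ by <= 0.01
  expect_identical(sum(cov$by_language$n), n)
})

test_that("term coverage classifies entries as direct, contextual or none", {
  fsn <- "900000000000003001"
  syn <- "900000000000013009"
  rf2 <- data.frame(
    id = as.character(1:3), effectiveTime = "t", active = "1", moduleId = "m",
    conceptId = c("101", "101", "102"), languageCode = "en",
    typeId = c(fsn, syn, fsn),
    term = c("Pain (finding)", "Dressing wound", "Fever (finding)"),
    caseSignificanceId = "cs", stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  utils::write.table(rf2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  cat_ <- load_concept_catalog(p)
  m <- map_table(data.frame(
    source_term = c("wound dressing", "fever clinic", "ghost"),
    target_concept_id = c("101", "102", NA),
    equivalence = c("full", "broader", "unmapped"),
    unmapped_category = c(NA, NA, "no_concept"),
    stringsAsFactors = FALSE))
  tc <- term_coverage(m, cat_)
  expect_identical(tc$table$match_type, c("direct_lexical", "contextual", "none"))
  expect_identical(tc$n_direct, 1L)
  expect_equal(tc$term_coverage_pct, round_half_up(100 / 3, 2))
  bl <- tc$by_language
  expect_identical(bl$n_direct[bl$language == "english"], 1L)
  expect_equal(bl$pct_of_language[bl$language == "english"],
               round_half_up(100 / 3, 2))
})

test_that("the unmapped breakdown requires categories and sums over the unmapped subset", {
  m <- map_table(data.frame(
    source_term = sprintf("u%02d", 1:6),
    target_concept_id = NA_character_,
    equivalence = "unmapped",
    unmapped_category = c(rep("ambiguous", 3), rep("multiconcept", 2),
                          "no_concept"),
    stringsAsFactors = FALSE))
  b <- unmapped_breakdown(m)
  expect_identical(b$category, c("ambiguous", "multiconcept", "no_concept"))
  expect_identical(b$n, c(3L, 2L, 1L))
  expect_equal(b$pct, c(50, round_half_up(100 / 3, 2), round_half_up(100 / 6, 2)))

  bad <- map_table(data.frame(source_term = "x", target_concept_id = NA_character_,
                              equivalence = "unmapped", stringsAsFactors = FALSE))
  expect_error(unmapped_breakdown(bad), "missing unmapped_category")
})

test_that("reports render in text, delimited and markdown forms", {
  cov <- concept_coverage(random_map_table(n_terms = 30, seed = 2))
  txt <- render_report(cov, "text")
  expect_true(any(grepl("Fully mapped", txt)))
  md <- render_report(cov, "markdown")
  expect_true(startsWith(md[1], "|"))
  expect_identical(length(md), 2L + 5L + 1L)
  del <- render_report(cov, "delimited")
  parsed <- utils::read.delim(text = paste(del, collapse = "\n"))
  expect_identical(nrow(parsed), 5L)
  expect_equal(parsed$total, cov$by_equivalence$total)
})
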