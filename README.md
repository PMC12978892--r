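# uitcoverage

Build a clinical **user interface terminology** (UIT) from mixed-script
free-text notes and audit its alignment with a reference terminology
(SNOMED CT conventions).

Clinicians write short idiosyncratic phrases, not reference-terminology
descriptions. A UIT is the curated set of phrases they actually use, each
linked to a concept. This package implements the complete desk-side method:

- **Corpus model** — de-identified outpatient documents with chief-complaint
  and present-illness sections, patient and department (FM/ER/IM) provenance,
  and a line-delimited interchange format.
- **Dictionary** — union of word-list sources (general word nets, concept
  descriptions, drug lists, reviewed abbreviations), deduplicated on a
  case-folded key; abbreviation harvesting (≥ 2 capitals, frequency > 100, on
  raw text); conservative spell checking (unique dictionary entry within one
  edit, Latin tokens of ≥ 4 characters only).
- **Segmentation** — greedy maximum matching for scripts written without
  spaces: at each position the longest dictionary entry wins; unknown runs
  merge by script class; offsets are 0-based half-open and reconstruct the
  input.
- **Candidate harvesting** — all 1–5-gram windows within a sentence; a
  candidate is filtered when > 50% of its tokens are stop words / punctuation
  / numbers or when it starts or ends with a stop word or preposition;
  surviving candidates are ranked by frequency within their N-stratum and
  selected when the rank percentile is ≤ 70 or the frequency is ≥ 300.
- **Mapping audit** — a map table of (term → concept, equivalence) pairs with
  categories full / broader / narrower / inexact / unmapped and one-to-many
  expansion; concept coverage, direct-lexical term coverage (bag-of-words
  equality with active descriptions), and an unmapped-failure breakdown
  (ambiguous / multiconcept / no concept). All percentages use the total
  entry count as denominator and round half-up to two decimals, as printed
  tables do.
- **Synthetic studies** — a seeded generator (`make_study()`) that emulates a
  bilingual three-department corpus with known ground truth: Zipfian planted
  terms in a private-use continuous script, copied-forward sentences,
  one-edit misspellings, planted abbreviations, and a concept catalog
  realizing designed equivalence fractions exactly. Every pipeline output is
  predictable in advance (`predict_pipeline_outputs()`), which is how the
  package tests itself without clinical data.

See `vignette("methods")` for the methodology and the generator's design.

## Worked example

```r
library(uitcoverage)

lex <- build_lexicon(list(wordnet_en = c("chest", "pain", "fever", "cough"),
                          concept_descriptions = "chest pain"))
corp <- corpus(doc_id = c("d1", "d2"), patient_id = c("p1", "p1"),
               department = c("FM", "FM"),
               chief_complaint = c("Chest Pain!!", "fever"),
               present_illness = c("cough and fever", "cough and fever"))
res <- run_uit_pipeline(corp, lex)
res$candidates[, c("surface", "n", "frequency", "filtered_reason",
                   "percentile_within_n", "selected")]
#>           surface n frequency   filtered_reason percentile_within_n selected
#> 1             and 1         1 stopword_fraction                  NA    FALSE
#> 2       and fever 2         1 boundary_stopword                  NA    FALSE
#> 3      chest pain 2         1              <NA>                 100    FALSE
#> 4           cough 1         1              <NA>                 100    FALSE
#> 5       cough and 2         1 boundary_stopword                  NA    FALSE
#> 6 cough and fever 3         1              <NA>                 100    FALSE
#> 7           fever 1         2              <NA>                  50     TRUE
res$dedup_report
#> <preprocess report> chars 45 -> 30 (33.33% removed), 1 duplicate sentences removed, 0 corrections
```

The second document's present illness was copied forward from the first visit
of the same patient, so deduplication removed it; "fever" then leads the
unigram stratum.

Coverage of a (toy) map table:

```r
m <- map_table(data.frame(
  source_term = c("chest pain", "fever", "cough"),
  target_concept_id = c("29857009", "386661006", NA),
  equivalence = c("full", "full", "unmapped"),
  unmapped_category = c(NA, NA, "no_concept")))
concept_coverage(m)
#> Concept coverage over 3 map entries
#>                  English                Thai                Total
#>   Fully mapped   2 (66.67)      0 (0.00)       2 (66.67)
#>   Broader        0 (0.00)       0 (0.00)       0 (0.00)
#>   Narrower       0 (0.00)       0 (0.00)       0 (0.00)
#>   Inexact        0 (0.00)       0 (0.00)       0 (0.00)
#>   Unmapped       1 (33.33)      0 (0.00)       1 (33.33)
#>   Fully mapped: 66.67%; full + partial: 66.67%; unmapped: 33.33%
#>   One-to-one terms: 2; one-to-many: 0 terms -> 0 pairs; unique concepts: 2
```

A full synthetic study, end to end:

```r
study <- make_study(study_design(seed = 1))
res <- run_uit_pipeline(study$corpus, study$lexicon)
identical(sort(res$candidates$surface[res$candidates$selected]),
          study$gold_selected)
#> [1] TRUE
```

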