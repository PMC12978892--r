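---
title: "Methods: harvesting an interface terminology and auditing its concept coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harvesting an interface terminology and auditing its concept coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(uitcoverage)
```

## The problem

Clinicians do not write reference-terminology descriptions; they write short,
idiosyncratic phrases — a *user interface terminology* (UIT) is the curated set
of such phrases, each linked to a concept of a reference terminology (here,
SNOMED CT conventions are used throughout). This package implements the full
desk-side methodology:

1. **Corpus**: de-identified outpatient notes with two free-text sections per
   document (chief complaint, present illness), with department and patient
   provenance.
2. **Dictionary**: the union of general word nets (Latin and continuous-script),
   reference-terminology descriptions, a drug list, and reviewed
   abbreviations, deduplicated on a case-folded key.
3. **Preprocessing**: abbreviation harvesting on the *raw* text (capitals must
   survive), then case folding and punctuation removal, then per-patient
   duplicate-sentence elimination, then dictionary spell checking.
4. **Segmentation**: greedy maximum matching — at each position the longest
   dictionary entry wins — with unknown runs merged by script class. This is
   the standard dictionary-driven approach for scripts written without spaces.
5. **Candidate terms**: all 1–5-gram windows within a sentence, filtered
   syntactically, ranked by frequency within each N-stratum, selected by a
   rank-percentile or absolute-frequency rule, then sent to clinical review.
6. **Mapping audit**: a map table of (source term → concept, equivalence)
   pairs supports concept-coverage and term-coverage statistics.

## Pipeline order and preprocessing choices

`run_uit_pipeline()` fixes the order: abbreviation harvest → normalize →
deduplicate → spell-check → tokenize → N-grams → filter → rank → select.
Abbreviations are harvested first because normalization case-folds the text and
destroys the ≥2-capitals signal. An abbreviation candidate must occur *strictly
more than* 100 times (`min_frequency = 100`).

Duplicate elimination is per patient and, by default, per *sentence*
(newline-delimited line): clinicians copy individual sentences forward between
visits, and removing whole entries would discard novel sentences appended to
copied ones. A sentence is dropped only when it already occurred in an
*earlier* document of the same patient; repeats within one document are kept
(they are genuine emphasis, not copy-forward). `granularity = "entry"`
compares whole sections instead.

Spell checking is deliberately conservative: a Latin token of ≥4 characters
that is out of dictionary is replaced only when *exactly one* dictionary entry
lies within Levenshtein distance 1. Continuous-script runs are never altered
(edit distance is meaningless across unsegmented text).

## Selection rule

Within each N-stratum, unfiltered candidates are ranked by frequency
(descending, lexicographic tie-break for determinism) and the percentile of a
candidate is `100 * rank / stratum size`. A candidate is selected when it is
unfiltered and

- its percentile is ≤ 70 (i.e. its rank lies within the top 70% of its
  stratum), **or**
- its absolute frequency is ≥ 300.

The percentile cut is interpreted on *rank*, not on the frequency
distribution: "top 70%" means the 70% most frequent distinct candidates of
that stratum. Both cuts are inclusive. Candidates with more than half
stop/punctuation/number tokens, or with a stop word or preposition at either
edge, are filtered before ranking.

## Mapping and coverage

A map table has one row per mapping *pair*; a term mapped to k concepts
contributes k rows, and the accounting identity

> one-to-one terms + one-to-many pairs + unmapped terms = total entries

is enforced at construction. Every coverage percentage uses the **total number
of entries (pairs)** as the denominator — including the per-language splits —
because the reporting convention gives each column of the equivalence ×
language table as a share of the whole terminology. Percentages are rounded
half *up* to two decimals (`round_half_up()`), matching printed tables rather
than R's round-half-even default.

A term's language is decided by script: any continuous-script character makes
it a continuous-script (Thai-side) term, so mixed-script terms count as Thai.
Term coverage uses a *direct lexical match*: the case-folded,
punctuation-stripped word multiset of the term equals that of some active
catalog description ("wound dressing" matches "Dressing wound"; "f/u" does not
match "Follow-up visit"). Unmapped entries are classified as `ambiguous`
(violates naming conventions, needs context), `multiconcept` (bundles several
clinical ideas), or `no_concept`.

## The synthetic study generator

Real clinical corpora cannot ship with a package, so `make_study()` generates
one whose *statistical structure* mirrors a bilingual three-department
outpatient corpus, with every downstream answer known in advance:

- **Synthetic continuous script.** Words are built from private-use code
  points: a head character (U+E000–U+E03F) followed by 1–3 tail characters
  (U+E040–U+E0BF). Because a dictionary unit starts with a head character and
  contains none elsewhere, greedy maximum matching provably recovers the
  planted segmentation — the generator needs no real-language resources.
- **Exclusive vocabulary.** Each planted term owns its tokens; no filler or
  other term reuses them. Hence the corpus frequency of a planted term equals
  its designed frequency *exactly*, even under noise.
- **Zipfian frequencies.** The rank-r term occurs `round(2000 / r^1.1)` times;
  exponent 1.1 gives the long-tail rank-frequency shape typical of clinical
  term distributions.
- **Noise with exact bookkeeping.** Copied-forward sentences are injected only
  after every generated sentence is unique per patient, so deduplication
  removes *exactly* the injected copies. Misspellings corrupt one character of
  a Latin word; planted jargon is kept at pairwise edit distance ≥ 3, so each
  corruption has a unique distance-1 correction. Planted abbreviations
  (uppercase, frequency 150 > 100) are recoverable by the harvesting rule.
- **Designed map and catalog.** Equivalence categories are allocated over
  entries by largest remainder from the designed fractions (default 85.5 /
  5.9 / 2.7 / 3.9 / 2.0), so `concept_coverage()` on the gold map reproduces
  them exactly; designated direct-match entries get a description that is a
  word-order permutation of the term, others get non-matching descriptions.

Default problem sizes (3 departments, 360 documents, 220 planted terms) are
the package's own choice: large enough that rank statistics and noise rates
are exercised meaningfully, small enough that a full study generates and runs
through the pipeline in seconds.

What the generator does **not** attempt: real Thai orthography (tone marks,
vowel reordering), realistic clinical semantics, or real SNOMED CT content.
It targets the statistics the pipeline is sensitive to, nothing else.

## Verification strategy

Two independent routes compute every answer:

- `reference_segment()` is a brute-force prefix-test segmenter sharing no code
  or index structures with `max_match_tokenize()`; the test suite checks
  equivalence on 1000 random (dictionary, string) cases.
- `predict_pipeline_outputs()` recomputes N-gram counts by direct window
  enumeration and applies the selection predicate directly; with zero noise
  the pipeline's selected set must equal this prediction exactly, and with 2%
  misspelling noise the high-frequency planted terms must still be recovered.

```{r, eval = FALSE}
study <- make_study(study_design(seed = 1))
res <- run_uit_pipeline(study$corpus, study$lexicon)
identical(sort(res$candidates$surface[res$candidates$selected]),
          study$gold_selected)
```

## Worked example

```{r}
lex <- build_lexicon(list(wordnet_en = c("chest", "pain", "fever", "cough"),
                          concept_descriptions = "chest pain"))
corp <- corpus(doc_id = c("d1", "d2"), patient_id = c("p1", "p1"),
               department = c("FM", "FM"),
               chief_complaint = c("Chest Pain!!", "fever"),
               present_illness = c("cough and fever", "cough and fever"))
res <- run_uit_pipeline(corp, lex)
subset(res$candidates, selected, select = c(surface, n, frequency))
```

```{r}
m <- map_table(data.frame(
  source_term = c("chest pain", "fever", "cough"),
  target_concept_id = c("29857009", "386661006", NA),
  equivalence = c("full", "full", "unmapped"),
  unmapped_category = c(NA, NA, "no_concept")))
concept_coverage(m)
```
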