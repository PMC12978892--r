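Package: uitcoverage
Title: User Interface Terminology Harvesting and SNOMED CT Coverage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a clinical user interface terminology (UIT)
    from mixed-script free-text notes and for auditing its alignment with a
    reference terminology such as SNOMED CT. Provides a corpus data model for
    chief-complaint / present-illness records, dictionary construction from
    multiple word-list sources with abbreviation harvesting and edit-distance
    spell correction, dictionary-driven maximum-matching segmentation of
    continuous-script text, N-gram candidate generation with stop-word and
    frequency/percentile selection rules, an RF2-style concept-catalog reader,
    a map-table model with equivalence categories (fully / broader / narrower /
    inexact / unmapped) and one-to-many expansion, concept- and term-coverage
    statistics, and a seeded synthetic-study generator that emulates the
    statistical structure of a bilingual primary-care corpus so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
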