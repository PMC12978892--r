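#' Concept coverage of a map table
#'
#' Computes the headline coverage statistics over the mapping-pair entries:
#' counts and percentages per equivalence category (fully / broader /
#' narrower / inexact / unmapped), overall and split by source-term language,
#' concept coverage (percent fully mapped), combined full-plus-partial
#' coverage, one-to-one / one-to-many accounting, and the unique-concept
#' count. The denominator for every percentage is the total number of map
#' entries (mapping pairs), and percentages are rounded half-up to two
#' decimals, matching how such tables are printed.
#'
#' @param x a `uit_map_table`.
#' @return a `uit_coverage_report` list with elements `by_equivalence` (data
#'   frame: equivalence x language counts and percents), `n_entries`,
#'   `concept_coverage_full_pct`, `concept_coverage_full_plus_partial_pct`,
#'   `unmapped_pct`, `partial_pct`, `n_one_to_one_terms`,
#'   `n_one_to_many_terms`, `n_one_to_many_pairs`, `n_unique_concepts`,
#'   `by_language` (entry counts per language).
#' @export
concept_coverage <- function(x) {
  x <- validate_map_table(x)
  .assert(nrow(x) > 0, "empty map table")
  acc <- attr(x, "accounting")
  langs <- c("english", "thai")
  tab <- matrix(0L, nrow = length(.equivalences), ncol = length(langs),
                dimnames = list(.equivalences, langs))
  cnt <- table(factor(x$equivalence, .equivalences),
               factor(x$source_language, langs))
  tab[rownames(cnt), colnames(cnt)] <- cnt
  total <- rowSums(tab)
  n <- acc$n_entries
  by_eq <- data.frame(
    equivalence = .equivalences,
    english = tab[, "english"], english_pct = .pct(tab[, "english"], n),
    thai = tab[, "thai"], thai_pct = .pct(tab[, "thai"], n),
    total = total, total_pct = .pct(total, n),
    row.names = NULL, stringsAsFactors = FALSE)
  partial <- sum(total[c("broader", "narrower", "inexact")])
  out <- list(
    by_equivalence = by_eq,
    n_entries = n,
    concept_coverage_full_pct = unname(.pct(total[["full"]], n)),
    partial_pct = unname(.pct(partial, n)),
    concept_coverage_full_plus_partial_pct = .pct(total[["full"]] + partial, n),
    unmapped_pct = unname(.pct(total[["unmapped"]], n)),
    n_one_to_one_terms = acc$n_one_to_one_terms,
    n_one_to_many_terms = acc$n_one_to_many_terms,
    n_one_to_many_pairs = acc$n_one_to_many_pairs,
    n_unique_concepts = acc$n_unique_concepts,
    by_language = data.frame(
      language = langs,
      n = as.integer(colSums(tab)),
      pct = .pct(colSums(tab), n),
      stringsAsFactors = FALSE)
  )
  class(out) <- "uit_coverage_report"
  out
}

#' @export
print.uit_coverage_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Term coverage: direct lexical matches against descriptions
#'
#' The percentage of map entries whose source term has a direct lexical
#' match (bag-of-words equality, see [detect_direct_lexical_match()]) with
#' an active catalog description. Sets `match_type` per entry:
#' `direct_lexical` for matches, `contextual` for mapped entries without a
#' lexical match, `none` for unmapped entries. Because the headline
#' percentage uses all entries as denominator while only one language may be
#' matchable, the per-language rate (matches / entries of that language) is
#' also reported.
#'
#' @param x a `uit_map_table`.
#' @param catalog a `uit_catalog`.
#' @return list with `table` (the map table with `match_type` and
#'   `description_id`), `n_direct`, `term_coverage_pct` (denominator: all
#'   entries), and `by_language` (per-language counts and rates).
#' @export
term_coverage <- function(x, catalog) {
  x <- validate_map_table(x)
  hit <- detect_direct_lexical_match(x$source_term, catalog)
  unm <- x$equivalence == "unmapped"
  x$match_type <- ifelse(unm, "none",
                         ifelse(hit$direct_match, "direct_lexical", "contextual"))
  x$description_id <- ifelse(unm, NA_character_, hit$description_id)
  n_direct <- sum(x$match_type == "direct_lexical")
  lang_n <- table(factor(x$source_language, c("english", "thai")))
  lang_hit <- table(factor(x$source_language[x$match_type == "direct_lexical"],
                           c("english", "thai")))
  list(
    table = x,
    n_direct = n_direct,
    term_coverage_pct = .pct(n_direct, nrow(x)),
    by_language = data.frame(
      language = c("english", "thai"),
      n_entries = as.integer(lang_n),
      n_direct = as.integer(lang_hit),
      pct_of_all_entries = .pct(as.integer(lang_hit), nrow(x)),
      pct_of_language = mapply(function(h, n) if (n > 0) .pct(h, n) else NA_real_,
                               as.integer(lang_hit), as.integer(lang_n)),
      stringsAsFactors = FALSE)
  )
}

#' Breakdown of unmapped entries by failure category
#'
#' Unmapped source terms fall into three classes: ambiguous terms that
#' violate naming conventions and need more context, terms bundling multiple
#' distinct clinical concepts (postcoordination candidates), and clinically
#' meaningful terms with no equivalent concept. Percentages are over the
#' unmapped subset, half-up to two decimals.
#'
#' @param x a `uit_map_table` whose unmapped entries carry
#'   `unmapped_category`.
#' @return data frame `category`, `n`, `pct`.
#' @export
unmapped_breakdown <- function(x) {
  x <- validate_map_table(x)
  unm <- x[x$equivalence == "unmapped", , drop = FALSE]
  .assert(!anyNA(unm$unmapped_category),
          "unmapped entries missing unmapped_category")
  .assert(all(unm$unmapped_category %in% .unmapped_categories),
          "unknown unmapped_category value(s)")
  cnt <- table(factor(unm$unmapped_category, .unmapped_categories))
  data.frame(category = .unmapped_categories,
             n = as.integer(cnt),
             pct = .pct(as.integer(cnt), nrow(unm)),
             stringsAsFactors = FALSE)
}

#' Render a coverage report
#'
#' @param report a `uit_coverage_report`.
#' @param format `"text"`, `"delimited"` (tab-separated, re-parsable) or
#'   `"markdown"`.
#' @return character vector of output lines.
#' @export
render_report <- function(report, format = c("text", "delimited", "markdown")) {
  format <- match.arg(format)
  be <- report$by_equivalence
  label <- c(full = "Fully mapped", broader = "Broader", narrower = "Narrower",
             inexact = "Inexact", unmapped = "Unmapped")[be$equivalence]
  if (format == "delimited") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(be, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    return(out)
  }
  fmt_cell <- function(n, p) sprintf("%d (%.2f)", n, p)
  rows <- cbind(label,
                fmt_cell(be$english, be$english_pct),
                fmt_cell(be$thai, be$thai_pct),
                fmt_cell(be$total, be$total_pct))
  if (format == "markdown") {
    hdr <- "| Concept equivalency | English | Thai | Total |"
    sep <- "|---|---|---|---|"
    body <- apply(rows, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    tail <- sprintf("| Total | %d | %d | %d (100) |",
                    report$by_language$n[1], report$by_language$n[2],
                    report$n_entries)
    return(c(hdr, sep, body, tail))
  }
  c(sprintf("Concept coverage over %d map entries", report$n_entries),
    sprintf("  %-14s English %-14s Thai %-14s Total %s",
            "", "", "", ""),
    apply(rows, 1, function(r) sprintf("  %-14s %-14s %-14s %s",
                                       r[1], r[2], r[3], r[4])),
    sprintf("  Fully mapped: %.2f%%; full + partial: %.2f%%; unmapped: %.2f%%",
            report$concept_coverage_full_pct,
            report$concept_coverage_full_plus_partial_pct,
            report$unmapped_pct),
    sprintf("  One-to-one terms: %d; one-to-many: %d terms -> %d pairs; unique concepts: %d",
            report$n_one_to_one_terms, report$n_one_to_many_terms,
            report$n_one_to_many_pairs, report$n_unique_concepts))
}
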