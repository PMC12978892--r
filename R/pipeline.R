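#' Run the full terminology-harvesting pipeline
#'
#' Executes the fixed pipeline order on a raw corpus: abbreviation harvesting
#' (before case normalization, so capitals survive), normalization,
#' per-patient duplicate-sentence elimination, dictionary spell checking,
#' maximum-matching tokenization, N-gram generation, syntactic filtering,
#' rank/percentile computation and threshold selection. Expert review of the
#' selected candidates remains an external step
#' ([export_review_sheet()] / [import_review_decisions()]).
#'
#' @param x a raw `uit_corpus`.
#' @param lexicon a `uit_lexicon`.
#' @param selection a [selection_config()].
#' @param tokenizer a [tokenizer_config()].
#' @param rules normalization rules ([normalization_rules()]).
#' @return list with `corpus` (preprocessed), `abbreviation_candidates`,
#'   `tokens` (per-document token frames), `candidates` (filtered, ranked,
#'   selection-flagged), `corpus_stats`, `dedup_report`, `spell_report`, and
#'   `log` (the configuration and step order actually used).
#' @export
#' @examples
#' lex <- build_lexicon(list(wordnet_en = c("chest", "pain", "fever")))
#' corp <- corpus("d1", "p1", "FM", "Chest Pain", "fever today")
#' res <- run_uit_pipeline(corp, lex)
#' subset(res$candidates, selected)
run_uit_pipeline <- function(x, lexicon,
                             selection = selection_config(),
                             tokenizer = tokenizer_config(),
                             rules = normalization_rules()) {
  validate_corpus(x)
  abbrev <- harvest_abbreviations(x)
  x <- normalize_corpus(x, rules)
  dd <- dedup_sentences(x)
  sc <- apply_spell_check(dd$corpus, lexicon)
  toks <- tokenize_corpus(sc$corpus, lexicon, tokenizer)
  cands <- generate_ngrams(toks, n_max = selection$n_max)
  cands <- filter_candidates(cands, selection)
  cands <- rank_candidates(cands)
  cands <- select_terms(cands, selection)
  list(corpus = sc$corpus,
       abbreviation_candidates = abbrev,
       tokens = toks,
       candidates = cands,
       corpus_stats = compute_corpus_stats(sc$corpus, toks),
       dedup_report = dd$report,
       spell_report = sc$report,
       log = list(order = c("harvest_abbreviations", "normalize",
                            "dedup_sentences", "apply_spell_check",
                            "tokenize", "ngrams", "filter", "rank", "select"),
                  selection = selection, tokenizer = tokenizer))
}
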