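.FSN_TYPE <- "900000000000003001"
.SYN_TYPE <- "900000000000013009"

#' Load an RF2-style concept description snapshot
#'
#' Reads a tab-separated description file following the SNOMED CT Release
#' Format 2 convention (columns `id`, `effectiveTime`, `active`, `moduleId`,
#' `conceptId`, `languageCode`, `typeId`, `term`, `caseSignificanceId`).
#' Fully-specified-name rows (FSN type) populate the concept table, with the
#' semantic tag parsed from the trailing parentheses of the FSN; all rows
#' (FSN and synonym) populate the description table. Inactive rows are
#' dropped by default and counted in the load report.
#'
#' @param path path to the TSV snapshot.
#' @param active_only drop rows with `active != 1` (default `TRUE`).
#' @return a `uit_catalog`: list with `concepts` (`concept_id`, `fsn`,
#'   `semantic_tag`, `active`), `descriptions` (`description_id`,
#'   `concept_id`, `term`, `language_code`, `type`, `active`), a prebuilt
#'   bag-of-words match index, and `load_report` (rows read / dropped).
#' @export
load_concept_catalog <- function(path, active_only = TRUE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", fileEncoding = "UTF-8")
  need <- c("id", "active", "conceptId", "term", "typeId")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0, "description file is missing column(s): %s",
          paste(miss, collapse = ", "))
  .catalog_from_rf2(df, active_only = active_only)
}

# shared constructor: `df` is an RF2-shaped description data frame
.catalog_from_rf2 <- function(df, active_only = TRUE) {
  if (!"languageCode" %in% names(df)) df$languageCode <- "en"
  n_read <- nrow(df)
  inactive <- df$active != "1"
  if (active_only) df <- df[!inactive, , drop = FALSE]
  fsn <- df[df$typeId == .FSN_TYPE, , drop = FALSE]
  tag <- sub("^.*\\(([^()]*)\\)\\s*$", "\\1", fsn$term)
  tag[tag == fsn$term] <- ""
  concepts <- data.frame(concept_id = fsn$conceptId, fsn = fsn$term,
                         semantic_tag = tag, active = fsn$active == "1",
                         stringsAsFactors = FALSE)
  concepts <- concepts[!duplicated(concepts$concept_id), , drop = FALSE]
  descriptions <- data.frame(description_id = df$id, concept_id = df$conceptId,
                             term = df$term, language_code = df$languageCode,
                             type = ifelse(df$typeId == .FSN_TYPE, "fsn", "synonym"),
                             active = df$active == "1",
                             stringsAsFactors = FALSE)
  out <- list(concepts = concepts, descriptions = descriptions,
              load_report = list(rows_read = n_read,
                                 rows_inactive_dropped = if (active_only) sum(inactive) else 0L))
  out$match_index <- .build_match_index(descriptions)
  class(out) <- "uit_catalog"
  out
}

#' @export
print.uit_catalog <- function(x, ...) {
  cat(sprintf("<uit_catalog> %d concepts, %d descriptions\n",
              nrow(x$concepts), nrow(x$descriptions)))
  invisible(x)
}

# normalization used for direct lexical matching: case-fold, strip
# punctuation, compare the word multiset (order-insensitive)
.bag_key <- function(terms) {
  t <- tolower(terms)
  t <- gsub("\\p{P}", " ", t, perl = TRUE)
  vapply(strsplit(trimws(t), "\\s+"), function(w)
    paste(sort(w), collapse = " "), character(1), USE.NAMES = FALSE)
}

.build_match_index <- function(descriptions) {
  act <- descriptions[descriptions$active, , drop = FALSE]
  keys <- .bag_key(act$term)
  env <- new.env(parent = emptyenv(), size = max(32L, 2L * nrow(act)))
  for (i in seq_len(nrow(act))) {
    k <- keys[i]
    if (is.null(env[[k]])) env[[k]] <- act$description_id[i]
  }
  env
}

#' Direct lexical match against catalog descriptions
#'
#' A term has a direct lexical match when its normalized word multiset
#' (case-insensitive, punctuation stripped, word order ignored) equals that
#' of some active description: "wound dressing" matches "Dressing wound",
#' but abbreviations or paraphrases ("f/u" vs "Follow-up visit") do not.
#'
#' @param terms character vector of source terms.
#' @param catalog a `uit_catalog`.
#' @return data frame `term`, `direct_match` (logical), `description_id`
#'   (first matching active description, `NA` if none).
#' @export
detect_direct_lexical_match <- function(terms, catalog) {
  keys <- .bag_key(terms)
  ids <- vapply(keys, function(k) {
    v <- catalog$match_index[[k]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  data.frame(term = terms, direct_match = !is.na(ids), description_id = ids,
             stringsAsFactors = FALSE)
}

#' Classify the language of a source term
#'
#' A term is tagged `thai` (continuous-script) when it contains at least one
#' continuous-script character, `english` otherwise; mixed-script terms thus
#' default to `thai`.
#'
#' @param terms non-empty character vector.
#' @return character vector over `c("thai", "english")`.
#' @export
classify_term_language <- function(terms) {
  .assert(all(nzchar(terms)), "cannot classify an empty term")
  ifelse(.has_continuous(terms), "thai", "english")
}

.equivalences <- c("full", "broader", "narrower", "inexact", "unmapped")
.unmapped_categories <- c("ambiguous", "multiconcept", "no_concept")

# bijective translation between file relationship labels and the
# equivalence vocabulary
.relationship_table <- data.frame(
  relationship = c("TARGET_EQUIVALENT", "TARGET_BROADER", "TARGET_NARROWER",
                   "TARGET_INEXACT"),
  equivalence = c("full", "broader", "narrower", "inexact"),
  stringsAsFactors = FALSE)

#' Construct and validate a terminology map table
#'
#' One row per mapping pair: a source term mapped to one target concept with
#' an equivalence category, or an unmapped row. A source term mapped to k
#' concepts contributes k rows (one-to-many mapping); a term is never both
#' mapped and unmapped. Entry accounting — one-to-one terms + one-to-many
#' pairs + unmapped terms = total entries — is checked on construction.
#'
#' @param entries data frame with columns `source_term`, `target_concept_id`
#'   (`NA` for unmapped), `equivalence` (`full`, `broader`, `narrower`,
#'   `inexact`, `unmapped`); optional `source_language`, `n`,
#'   `unmapped_category` (`ambiguous`, `multiconcept`, `no_concept`),
#'   `match_type`. Missing optional columns are derived (`source_language`
#'   from the script, `n` from the token count) or set `NA`.
#' @return a validated `uit_map_table` data frame.
#' @export
map_table <- function(entries) {
  need <- c("source_term", "target_concept_id", "equivalence")
  .assert(all(need %in% names(entries)), "map table needs column(s): %s",
          paste(setdiff(need, names(entries)), collapse = ", "))
  entries$source_term <- as.character(entries$source_term)
  entries$target_concept_id <- as.character(entries$target_concept_id)
  entries$equivalence <- as.character(entries$equivalence)
  if (is.null(entries$source_language))
    entries$source_language <- classify_term_language(entries$source_term)
  if (is.null(entries$n))
    entries$n <- lengths(strsplit(entries$source_term, "\\s+"))
  if (is.null(entries$match_type))
    entries$match_type <- ifelse(entries$equivalence == "unmapped", "none",
                                 NA_character_)
  if (is.null(entries$unmapped_category))
    entries$unmapped_category <- NA_character_
  rownames(entries) <- NULL
  class(entries) <- c("uit_map_table", "data.frame")
  validate_map_table(entries)
}

#' @rdname map_table
#' @param x a `uit_map_table`.
#' @return `validate_map_table()` returns `x` after checking the invariants,
#'   with the accounting counts attached as attribute `accounting`
#'   (`n_entries`, `n_one_to_one_terms`, `n_one_to_many_terms`,
#'   `n_one_to_many_pairs`, `n_unmapped`, `n_unique_concepts`).
#' @export
validate_map_table <- function(x) {
  .assert(all(x$equivalence %in% .equivalences),
          "unknown equivalence value(s): %s",
          paste(setdiff(unique(x$equivalence), .equivalences), collapse = ", "))
  unm <- x$equivalence == "unmapped"
  .assert(all(is.na(x$target_concept_id[unm])),
          "unmapped entries must have no target concept")
  .assert(all(!is.na(x$target_concept_id[!unm])),
          "mapped entries must carry a target concept")
  .assert(all(x$match_type[unm] %in% "none"),
          "unmapped entries must have match_type 'none'")
  .assert(all(is.na(x$unmapped_category) | unm),
          "unmapped_category may only be set on unmapped entries")
  both <- intersect(unique(x$source_term[unm]), unique(x$source_term[!unm]))
  .assert(length(both) == 0,
          "source term(s) both mapped and unmapped: %s",
          paste(utils::head(both, 3), collapse = ", "))
  mapped_counts <- table(x$source_term[!unm])
  acc <- list(
    n_entries = nrow(x),
    n_one_to_one_terms = sum(mapped_counts == 1),
    n_one_to_many_terms = sum(mapped_counts > 1),
    n_one_to_many_pairs = sum(mapped_counts[mapped_counts > 1]),
    n_unmapped = sum(unm),
    n_unique_concepts = length(unique(x$target_concept_id[!unm]))
  )
  .assert(acc$n_one_to_one_terms + acc$n_one_to_many_pairs + acc$n_unmapped ==
            acc$n_entries, "map-table entry accounting failed")
  attr(x, "accounting") <- acc
  x
}

#' @export
print.uit_map_table <- function(x, ...) {
  a <- attr(x, "accounting")
  if (is.null(a)) a <- attr(validate_map_table(x), "accounting")
  cat(sprintf(paste0("<uit_map_table> %d entries: %d one-to-one, ",
                     "%d one-to-many pairs (%d terms), %d unmapped; ",
                     "%d unique concepts\n"),
              a$n_entries, a$n_one_to_one_terms, a$n_one_to_many_pairs,
              a$n_one_to_many_terms, a$n_unmapped, a$n_unique_concepts))
  invisible(x)
}

#' Read / write a map table file
#'
#' The file mirrors a mapping-tool export: tab-separated with columns
#' `source_term`, `source_language`, `n`, `target_concept_id`,
#' `relationship`, `status`, `unmapped_category`. Relationship labels
#' translate bijectively to the equivalence vocabulary
#' (`TARGET_EQUIVALENT` = full, `TARGET_BROADER` = broader,
#' `TARGET_NARROWER` = narrower, `TARGET_INEXACT` = inexact; an empty
#' relationship with status `UNMAPPED` is an unmapped row).
#'
#' @param path file path.
#' @return `load_map_table()` returns a `uit_map_table`;
#'   `write_map_table()` returns `path` invisibly. They are inverses.
#' @export
load_map_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          quote = "", fileEncoding = "UTF-8")
  need <- c("source_term", "target_concept_id", "relationship", "status")
  .assert(all(need %in% names(df)), "map file needs column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  unm <- df$status == "UNMAPPED"
  eq <- rep(NA_character_, nrow(df))
  eq[unm] <- "unmapped"
  m <- match(df$relationship[!unm], .relationship_table$relationship)
  .assert(!anyNA(m), "unknown relationship value(s): %s",
          paste(unique(df$relationship[!unm][is.na(m)]), collapse = ", "))
  eq[!unm] <- .relationship_table$equivalence[m]
  entries <- data.frame(
    source_term = df$source_term,
    target_concept_id = ifelse(unm, NA_character_, df$target_concept_id),
    equivalence = eq,
    stringsAsFactors = FALSE)
  if ("source_language" %in% names(df)) entries$source_language <- df$source_language
  if ("n" %in% names(df)) entries$n <- as.integer(df$n)
  if ("unmapped_category" %in% names(df)) {
    uc <- df$unmapped_category
    uc[!nzchar(uc)] <- NA_character_
    entries$unmapped_category <- uc
  }
  map_table(entries)
}

#' @rdname load_map_table
#' @param x a `uit_map_table`.
#' @export
write_map_table <- function(x, path) {
  x <- validate_map_table(x)
  unm <- x$equivalence == "unmapped"
  rel <- .relationship_table$relationship[match(x$equivalence,
                                                .relationship_table$equivalence)]
  out <- data.frame(
    source_term = x$source_term,
    source_language = x$source_language,
    n = x$n,
    target_concept_id = ifelse(unm, "", x$target_concept_id),
    relationship = ifelse(unm, "", rel),
    status = ifelse(unm, "UNMAPPED", "MAPPED"),
    unmapped_category = ifelse(is.na(x$unmapped_category), "",
                               x$unmapped_category),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
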