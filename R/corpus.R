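#' Clinical document corpus
#'
#' A corpus holds de-identified outpatient notes, one row per document, with
#' the two free-text sections the terminology is harvested from: the chief
#' complaint and the present illness. Documents carry patient and department
#' provenance (family medicine `FM`, emergency room `ER`, internal medicine
#' `IM`); patient ids may repeat across documents, document ids may not.
#'
#' @param doc_id character vector of unique document identifiers.
#' @param patient_id character vector of patient identifiers (repeats allowed).
#' @param department character vector with values in `"FM"`, `"ER"`, `"IM"`.
#' @param chief_complaint,present_illness character vectors of free text; for
#'   every document at least one of the two must be non-empty.
#' @param metadata optional named list of free-form provenance.
#' @return An object of class `uit_corpus`: a data frame with the five
#'   document columns and a `metadata` attribute.
#' @seealso [read_corpus()], [write_corpus()], [compute_corpus_stats()]
#' @export
#' @examples
#' corpus(doc_id = "d1", patient_id = "p1", department = "FM",
#'        chief_complaint = "chest pain", present_illness = "pain for 2 days")
corpus <- function(doc_id = character(), patient_id = character(),
                   department = character(), chief_complaint = character(),
                   present_illness = character(), metadata = list()) {
  df <- data.frame(
    doc_id = as.character(doc_id),
    patient_id = as.character(patient_id),
    department = as.character(department),
    chief_complaint = as.character(chief_complaint),
    present_illness = as.character(present_illness),
    stringsAsFactors = FALSE
  )
  attr(df, "metadata") <- metadata
  class(df) <- c("uit_corpus", "data.frame")
  validate_corpus(df)
}

.departments <- c("FM", "ER", "IM")

#' Validate a corpus object
#'
#' Checks the corpus invariants: unique document ids, known department codes,
#' and at least one non-empty text section per document.
#'
#' @param x a `uit_corpus`.
#' @param allow_empty allow documents whose two sections are both empty;
#'   used downstream of duplicate elimination, which can empty a document.
#' @return `x`, invisibly checked (errors on violation).
#' @export
validate_corpus <- function(x, allow_empty = FALSE) {
  .assert(all(c("doc_id", "patient_id", "department", "chief_complaint",
                "present_illness") %in% names(x)),
          "corpus is missing required columns")
  .assert(!anyDuplicated(x$doc_id), "duplicate doc_id in corpus")
  bad <- setdiff(unique(x$department), .departments)
  .assert(length(bad) == 0, "unknown department code(s): %s",
          paste(bad, collapse = ", "))
  if (!allow_empty) {
    empty <- !nzchar(trimws(x$chief_complaint)) & !nzchar(trimws(x$present_illness))
    .assert(!any(empty), "document(s) with both text sections empty: %s",
            paste(utils::head(x$doc_id[empty], 3), collapse = ", "))
  }
  x
}

#' Read a corpus from a line-delimited record file
#'
#' The file is UTF-8, one document per line, tab-separated, with a header row
#' naming the five document fields. Embedded tabs and newlines in the text
#' sections are backslash-escaped. Records in which both text sections are
#' empty are excluded (they carry no harvestable content); the number excluded
#' is recorded in the returned corpus's metadata as `n_excluded`.
#'
#' @param path path to a corpus file written by [write_corpus()].
#' @return a `uit_corpus`.
#' @export
read_corpus <- function(path) {
  .assert(file.exists(path), "no such corpus file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  .assert(length(lines) >= 1, "corpus file is empty (missing header): %s", path)
  fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("doc_id", "patient_id", "department", "chief_complaint",
            "present_illness")
  .assert(all(need %in% fields), "corpus header lacks field(s): %s",
          paste(setdiff(need, fields), collapse = ", "))
  body <- lines[-1]
  recs <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(recs)
  # trailing empty fields are dropped by strsplit; pad them back
  short <- which(nf < length(fields))
  for (i in short) recs[[i]] <- c(recs[[i]], rep("", length(fields) - nf[i]))
  bad <- which(lengths(recs) != length(fields))
  .assert(length(bad) == 0, "malformed record at line %d", bad[1] + 1L)
  m <- do.call(rbind, recs)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- fields
  df <- df[need]
  df$chief_complaint <- .unescape_field(df$chief_complaint)
  df$present_illness <- .unescape_field(df$present_illness)
  bad_dept <- which(!(df$department %in% .departments))
  .assert(length(bad_dept) == 0, "unknown department code at line %d: %s",
          bad_dept[1] + 1L, df$department[bad_dept[1]])
  empty <- !nzchar(trimws(df$chief_complaint)) & !nzchar(trimws(df$present_illness))
  df <- df[!empty, , drop = FALSE]
  rownames(df) <- NULL
  out <- corpus(df$doc_id, df$patient_id, df$department,
                df$chief_complaint, df$present_illness,
                metadata = list(source = path, n_excluded = sum(empty)))
  out
}

#' Write a corpus to a line-delimited record file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` field by field.
#'
#' @param x a `uit_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  validate_corpus(x)
  header <- "doc_id\tpatient_id\tdepartment\tchief_complaint\tpresent_illness"
  rows <- paste(x$doc_id, x$patient_id, x$department,
                .escape_field(x$chief_complaint),
                .escape_field(x$present_illness), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(c(header, rows)), con, useBytes = TRUE)
  invisible(path)
}

#' @export
print.uit_corpus <- function(x, ...) {
  cat(sprintf("<uit_corpus> %d documents, %d patients, departments: %s\n",
              nrow(x), length(unique(x$patient_id)),
              paste(sort(unique(x$department)), collapse = "/")))
  invisible(x)
}

#' Summarize per-department document and word counts
#'
#' The arithmetic core of the corpus characteristics table: given one row per
#' department with document counts, total word counts and continuous-script
#' word counts, append an overall row and the continuous-script and
#' departmental shares. A word counts as continuous-script if it contains at
#' least one continuous-script character (e.g. Thai).
#'
#' @param counts data frame with columns `department`, `n_documents`,
#'   `total_words`, `total_continuous_words`.
#' @return the same data frame plus a `Total` row and columns
#'   `continuous_word_pct` (percent of that department's words, 2 decimals)
#'   and `document_share_pct` (percent of all documents, 1 decimal).
#' @export
#' @examples
#' department_summary(data.frame(
#'   department = c("FM", "ER", "IM"),
#'   n_documents = c(30346, 34829, 118382),
#'   total_words = c(1723895, 2750896, 10471768),
#'   total_continuous_words = c(1016914, 1752756, 4154255)))
department_summary <- function(counts) {
  need <- c("department", "n_documents", "total_words", "total_continuous_words")
  .assert(all(need %in% names(counts)), "counts lacks column(s): %s",
          paste(setdiff(need, names(counts)), collapse = ", "))
  counts <- counts[need]
  tot <- data.frame(department = "Total",
                    n_documents = sum(counts$n_documents),
                    total_words = sum(counts$total_words),
                    total_continuous_words = sum(counts$total_continuous_words),
                    stringsAsFactors = FALSE)
  out <- rbind(counts, tot)
  out$continuous_word_pct <- round_half_up(
    100 * out$total_continuous_words / out$total_words, 2)
  out$document_share_pct <- round_half_up(
    100 * out$n_documents / tot$n_documents, 1)
  out
}

# does each surface contain >= 1 continuous-script code point?
.has_continuous <- function(surfaces) {
  vapply(surfaces, function(s) any(.is_continuous_cp(utf8ToInt(s))),
         logical(1), USE.NAMES = FALSE)
}

#' Corpus characteristics by department
#'
#' Computes the word-level corpus characteristics as conventionally reported
#' for clinical corpora: per department and overall, the number of patients and
#' documents, documents per patient (median and IQR over patients), unique
#' and total words with the continuous-script subset and its percentage, and
#' words per document (median and IQR over documents). A "word" is one token
#' emitted by the segmenter, not a whitespace split, so the function takes
#' the per-document token lists produced by [tokenize_corpus()].
#'
#' @param x a `uit_corpus`.
#' @param tokens_per_doc list parallel to the corpus rows; each element either
#'   a character vector of token surfaces or a data frame with a `surface`
#'   column (as returned by [tokenize_corpus()]).
#' @return a `uit_corpus_stats` object: a data frame with one row per
#'   department plus `Total`. The `Total` row counts each patient once even if
#'   seen in several departments; the per-department patient sum is kept in
#'   attribute `n_patients_by_department_sum`.
#' @export
compute_corpus_stats <- function(x, tokens_per_doc) {
  validate_corpus(x, allow_empty = TRUE)
  .assert(length(tokens_per_doc) == nrow(x),
          "tokens_per_doc has %d elements but corpus has %d documents",
          length(tokens_per_doc), nrow(x))
  toks <- lapply(tokens_per_doc, function(t) {
    if (is.data.frame(t)) as.character(t$surface) else as.character(t)
  })
  depts <- c(intersect(.departments, unique(x$department)))
  one <- function(idx, label, patients_dedup = TRUE) {
    tt <- toks[idx]
    all_tok <- unlist(tt, use.names = FALSE)
    uniq <- unique(all_tok)
    cs_uniq <- if (length(uniq)) sum(.has_continuous(uniq)) else 0L
    cs_tot <- if (length(uniq)) {
      cs_set <- uniq[.has_continuous(uniq)]
      sum(all_tok %in% cs_set)
    } else 0L
    wpd <- .med_iqr(lengths(tt))
    dpp <- .med_iqr(as.integer(table(x$patient_id[idx])))
    data.frame(
      department = label,
      n_patients = length(unique(x$patient_id[idx])),
      n_documents = length(idx),
      docs_per_patient_median = dpp["median"],
      docs_per_patient_q1 = dpp["q1"],
      docs_per_patient_q3 = dpp["q3"],
      unique_words = length(uniq),
      unique_continuous_words = cs_uniq,
      unique_continuous_pct = .pct(cs_uniq, length(uniq)),
      total_words = length(all_tok),
      total_continuous_words = cs_tot,
      total_continuous_pct = .pct(cs_tot, length(all_tok)),
      words_per_doc_median = wpd["median"],
      words_per_doc_q1 = wpd["q1"],
      words_per_doc_q3 = wpd["q3"],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  rows <- lapply(depts, function(d) one(which(x$department == d), d))
  rows <- c(rows, list(one(seq_len(nrow(x)), "Total")))
  out <- do.call(rbind, rows)
  attr(out, "n_patients_by_department_sum") <-
    sum(out$n_patients[out$department != "Total"])
  class(out) <- c("uit_corpus_stats", "data.frame")
  out
}
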