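#' @importFrom rlang .data
NULL

# lines beginning with this prefix are provenance headers written by the
# command-line interface; '#' alone cannot be a comment char because it is
# the word-boundary marker and a legal first character of a cue label
header_prefix <- "#%"

read_tsv_skipping_header <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, header_prefix)]
  if (length(lines) == 0L) rlang::abort(sprintf("'%s' is empty.", path))
  readr::read_tsv(I(paste0(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}

require_columns <- function(tbl, wanted, path) {
  missing <- setdiff(wanted, names(tbl))
  if (length(missing)) {
    rlang::abort(sprintf(
      "'%s' is missing column(s) %s; found columns: %s.",
      path, paste(missing, collapse = ", "), paste(names(tbl), collapse = ", ")
    ))
  }
}

#' Read a pronunciation corpus from TSV
#'
#' The corpus format is UTF-8 tab-separated with header columns
#' `Speaker`, `Outcome`, `Pronunciation`, `Frequency`. One row is one
#' pronounced word token: repeated (speaker, outcome) rows are kept as
#' separate tokens. Outcomes (meanings) are case-folded. Every
#' pronunciation is validated by [parse_ipa()] at read time. Lines starting
#' with `#%` are treated as provenance headers and skipped.
#'
#' @param path Path to the TSV file.
#' @param diacritics Passed to [parse_ipa()] for validation (`"strip"` or
#'   `"keep"`); stored as corpus metadata.
#' @return A tibble with columns `speaker`, `outcome`, `pronunciation`,
#'   `frequency`, and a `metadata` attribute recording provenance.
#' @export
read_corpus <- function(path, diacritics = c("strip", "keep")) {
  diacritics <- rlang::arg_match(diacritics)
  raw <- read_tsv_skipping_header(path)
  require_columns(raw, c("Speaker", "Outcome", "Pronunciation", "Frequency"), path)
  if (nrow(raw) == 0L) rlang::abort(sprintf("'%s' contains no records.", path))
  freq <- suppressWarnings(as.numeric(gsub(",", "", raw$Frequency)))
  bad <- which(is.na(freq) | freq <= 0)
  if (length(bad)) {
    rlang::abort(sprintf(
      "non-positive or unparseable Frequency at data row %d of '%s' (value '%s').",
      bad[1], path, raw$Frequency[bad[1]]
    ))
  }
  for (i in seq_len(nrow(raw))) {
    tryCatch(
      parse_ipa(raw$Pronunciation[i], diacritics = diacritics),
      error = function(e) {
        rlang::abort(sprintf(
          "invalid Pronunciation at data row %d of '%s': %s",
          i, path, conditionMessage(e)
        ))
      }
    )
  }
  out <- tibble::tibble(
    speaker = raw$Speaker,
    outcome = tolower(raw$Outcome),
    pronunciation = raw$Pronunciation,
    frequency = freq
  )
  attr(out, "metadata") <- list(path = path, diacritics = diacritics)
  out
}

#' Write a pronunciation corpus to TSV
#'
#' @param corpus Tibble with `speaker`, `outcome`, `pronunciation`,
#'   `frequency` columns.
#' @param path Output path.
#' @param header_lines Optional character vector written first, each
#'   prefixed with `#%`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, header_lines = NULL) {
  validate_corpus(corpus)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0(header_prefix, " ", header_lines), con)
  }
  writeLines("Speaker\tOutcome\tPronunciation\tFrequency", con)
  writeLines(
    paste(corpus$speaker, corpus$outcome, corpus$pronunciation,
      format(corpus$frequency, trim = TRUE, scientific = FALSE),
      sep = "\t"
    ),
    con
  )
  invisible(path)
}

validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    rlang::abort("corpus must be a data frame with at least one record.")
  }
  need <- c("speaker", "outcome", "pronunciation", "frequency")
  missing <- setdiff(need, names(corpus))
  if (length(missing)) {
    rlang::abort(sprintf(
      "corpus is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  if (any(!is.finite(corpus$frequency) | corpus$frequency <= 0)) {
    rlang::abort("corpus frequencies must all be positive and finite.")
  }
  invisible(corpus)
}

#' Read a ratings table from TSV
#'
#' Format: tab-separated with header `Rater`, `Sample`, `Score`; one row per
#' individual judgment on a bounded Likert scale.
#'
#' @param path Path to the TSV file.
#' @param scale Length-2 numeric, inclusive score bounds (default 1--7).
#' @return A tibble with columns `rater`, `sample`, `score`.
#' @export
read_ratings <- function(path, scale = c(1, 7)) {
  raw <- read_tsv_skipping_header(path)
  require_columns(raw, c("Rater", "Sample", "Score"), path)
  score <- suppressWarnings(as.numeric(raw$Score))
  bad <- which(is.na(score) | score < scale[1] | score > scale[2])
  if (length(bad)) {
    rlang::abort(sprintf(
      "Score out of [%s, %s] at data row %d of '%s' (value '%s').",
      scale[1], scale[2], bad[1], path, raw$Score[bad[1]]
    ))
  }
  tibble::tibble(rater = raw$Rater, sample = raw$Sample, score = score)
}

#' Write a ratings table to TSV
#' @param ratings Tibble with `rater`, `sample`, `score`.
#' @param path Output path.
#' @param header_lines Optional `#%` provenance header lines.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path, header_lines = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0(header_prefix, " ", header_lines), con)
  }
  writeLines("Rater\tSample\tScore", con)
  writeLines(paste(ratings$rater, ratings$sample, ratings$score, sep = "\t"), con)
  invisible(path)
}

#' Divide a meaning's total frequency over its pronunciation variants
#'
#' The total corpus frequency of a meaning is split equally over all its
#' distinct pronunciations, so that variant tokens compete on even footing:
#' e.g. a word of frequency 580,000 with 58 pronunciations gives 10,000
#' per pronunciation.
#'
#' @param total_frequency Positive total frequency (vectorised).
#' @param n_pronunciations Positive integer count of distinct pronunciations.
#' @return `total_frequency / n_pronunciations`.
#' @export
split_frequency <- function(total_frequency, n_pronunciations) {
  if (any(!is.finite(total_frequency) | total_frequency <= 0)) {
    rlang::abort("`total_frequency` must be positive and finite.")
  }
  if (any(n_pronunciations < 1 | n_pronunciations != as.integer(n_pronunciations))) {
    rlang::abort("`n_pronunciations` must be a positive integer.")
  }
  total_frequency / n_pronunciations
}

#' Tokenize an elicitation paragraph into word tokens
#'
#' Splits on whitespace, strips leading/trailing punctuation and symbol
#' characters, case-folds, and drops empty tokens. Idempotent on its own
#' space-joined output.
#'
#' @param text A character string (or vector, concatenated with spaces).
#' @return Character vector of word tokens (possibly empty).
#' @export
tokenize_paragraph <- function(text) {
  text <- paste(text, collapse = " ")
  if (!nzchar(trimws(text))) return(character(0))
  toks <- strsplit(text, "[[:space:]]+")[[1]]
  toks <- gsub("^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "", toks, perl = TRUE)
  toks <- tolower(toks[nzchar(toks)])
  toks
}
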