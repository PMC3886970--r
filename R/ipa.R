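#' IPA modifier letters treated as diacritics
#'
#' Spacing modifier letters and length marks that attach to the preceding
#' base segment during parsing, in addition to all Unicode combining marks
#' (general category M, matched via `\\p{M}`). The set is deliberately an
#' explicit table: IPA itself never enumerates "the diacritics", so the
#' package documents its own and lets callers extend it via the
#' `extra_diacritics` argument of [parse_ipa()].
#'
#' @format A character vector of single codepoints.
#' @export
ipa_modifier_chars <- c(
  # secondary articulation / release
  "ʰ", "ʱ", "ʲ", "ʳ", "ʴ", "ʵ", "ʶ",
  "ʷ", "ˠ", "ˡ", "ˤ", "ˀ", "ʼ", "ⁿ",
  "ˢ",
  # length and prosodic marks
  "ː", "ˑ",
  # rhoticity / no-audible-release
  "˞", "˺"
)

ipa_boundary <- "#"

is_combining_mark <- function(ch) {
  grepl("^\\p{M}$", ch, perl = TRUE)
}

is_diacritic_char <- function(ch, extra = character()) {
  is_combining_mark(ch) | ch %in% ipa_modifier_chars | ch %in% extra
}

#' Parse an IPA transcription into a segment sequence
#'
#' Splits a UTF-8 IPA string into phone segments, one per base character.
#' Combining marks and IPA modifier letters ([ipa_modifier_chars]) are
#' diacritics: in `"keep"` mode they stay attached to the preceding base
#' segment, in `"strip"` mode they are discarded. Tie bars (combining
#' double marks) attach to the base on their left. Enclosing brackets
#' (`[...]`, `/.../`) and whitespace are removed before parsing.
#'
#' Multi-character units (affricates, diphthongs) are one segment per base
#' character unless `digraphs` supplies explicit unit strings, which are
#' merged greedily left-to-right, longest first.
#'
#' @param text A single IPA string, e.g. `"[wɪθ]"`.
#' @param diacritics `"strip"` (default) or `"keep"`.
#' @param extra_diacritics Additional codepoints to treat as diacritics.
#' @param digraphs Optional character vector of multi-segment units to merge
#'   (compared against the rendered segments after diacritic handling).
#' @return A character vector of segments (length >= 1).
#' @examples
#' parse_ipa("[wɪθ]")
#' parse_ipa("t̪a", diacritics = "keep")
#' @export
parse_ipa <- function(text, diacritics = c("strip", "keep"),
                      extra_diacritics = character(), digraphs = NULL) {
  diacritics <- rlang::arg_match(diacritics)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    rlang::abort("`text` must be a single non-NA string.")
  }
  text <- gsub("^[\\[/⟨]+|[\\]/⟩]+$", "", trimws(text), perl = TRUE)
  text <- gsub("[[:space:]]+", "", text)
  if (!nzchar(text)) {
    rlang::abort("empty transcription: no segments to parse.")
  }
  chars <- strsplit(enc2utf8(text), "", fixed = FALSE)[[1]]
  if (any(chars == ipa_boundary)) {
    rlang::abort(sprintf(
      "'%s' is reserved as the word-boundary marker and may not occur inside a transcription.",
      ipa_boundary
    ))
  }
  segs <- character(0)
  for (ch in chars) {
    if (is_diacritic_char(ch, extra_diacritics)) {
      if (length(segs) == 0L) {
        rlang::abort(sprintf(
          "transcription starts with combining/modifier mark U+%04X with no base segment.",
          utf8ToInt(ch)
        ))
      }
      if (diacritics == "keep") {
        segs[length(segs)] <- paste0(segs[length(segs)], ch)
      }
    } else {
      segs <- c(segs, ch)
    }
  }
  if (!is.null(digraphs) && length(digraphs)) {
    segs <- merge_digraphs(segs, digraphs)
  }
  segs
}

# greedy longest-match merge of adjacent segments into declared units
merge_digraphs <- function(segs, digraphs) {
  digraphs <- digraphs[order(-nchar(digraphs))]
  out <- character(0)
  i <- 1L
  n <- length(segs)
  while (i <= n) {
    merged <- FALSE
    for (d in digraphs) {
      for (k in seq.int(min(n - i + 1L, 4L), 2L)) {
        if (paste0(segs[i:(i + k - 1L)], collapse = "") == d) {
          out <- c(out, d)
          i <- i + k
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) {
      out <- c(out, segs[i])
      i <- i + 1L
    }
  }
  out
}

#' Render a segment sequence back to a transcription string
#'
#' Inverse of [parse_ipa()] in `"keep"` mode: `parse_ipa(render_ipa(x),
#' diacritics = "keep")` reproduces `x`.
#'
#' @param segments Character vector of segments.
#' @return A single string.
#' @export
render_ipa <- function(segments) {
  paste0(segments, collapse = "")
}

# parse every pronunciation of a character vector; returns a list of
# segment vectors (internal workhorse for corpus-level operations)
ipa_segment_list <- function(x, diacritics = "strip", digraphs = NULL) {
  lapply(x, parse_ipa, diacritics = diacritics, digraphs = digraphs)
}
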