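#' Extract n-gram cues from a segment sequence
#'
#' Converts a transcription into the set of phone n-gram cues presented to
#' the listener model. For `n >= 2` the sequence is padded with one
#' boundary marker `#` on each side and every contiguous window of length
#' `n` is emitted, so a k-segment word yields k trigram windows (k + 1
#' bigram windows); a one-segment word yields the single trigram `#x#`.
#' Unigram cues are the segments themselves, without boundary (a boundary
#' unigram would co-occur with every outcome and discriminate nothing).
#'
#' Cues are presence/absence types: a window occurring twice in one word
#' is one cue. Passing several values of `n` unions the cue registries
#' (e.g. `n = c(1, 3)` for unigrams plus trigrams).
#'
#' @param segments Character vector of segments (from [parse_ipa()]), or a
#'   single unparsed IPA string.
#' @param n n-gram order(s), each in 1, 2, 3.
#' @param diacritics Used only when `segments` is an unparsed string.
#' @return Character vector of distinct cue labels.
#' @examples
#' extract_cues(c("w", "ɪ", "θ"), n = 3)
#' @export
extract_cues <- function(segments, n = 3, diacritics = c("strip", "keep")) {
  if (!all(n %in% 1:3)) {
    rlang::abort("`n` must contain only values in {1, 2, 3}.")
  }
  if (is.character(segments) && length(segments) == 1L &&
    nchar(segments) > 1L && !segments %in% c(ipa_boundary)) {
    # tolerate a raw string for interactive use
    segments <- parse_ipa(segments, diacritics = rlang::arg_match(diacritics))
  }
  if (length(segments) == 0L) rlang::abort("empty segment sequence.")
  out <- character(0)
  for (k in sort(unique(n))) {
    if (k == 1L) {
      out <- c(out, segments)
    } else {
      padded <- c(ipa_boundary, segments, ipa_boundary)
      idx <- seq_len(length(padded) - k + 1L)
      out <- c(out, vapply(
        idx,
        function(i) paste0(padded[i:(i + k - 1L)], collapse = ""),
        character(1)
      ))
    }
  }
  unique(out)
}

# cue sets for a whole pronunciation column: list of character vectors
cue_set_list <- function(pronunciations, n = 3, diacritics = "strip",
                         digraphs = NULL) {
  segs <- ipa_segment_list(pronunciations, diacritics = diacritics, digraphs = digraphs)
  lapply(segs, extract_cues, n = n)
}
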