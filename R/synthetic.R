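#' Default synthetic segment inventory
#'
#' A small plain-ASCII-compatible IPA inventory (9 vowels would be
#' unrealistic; 5 vowels + 14 consonants) used by the synthetic corpus
#' generators. Words are built with alternating consonant/vowel structure
#' so they are pronounceable strings rather than arbitrary draws.
#'
#' @return Character vector of segments.
#' @export
default_inventory <- function() {
  c(
    "p", "t", "k", "b", "d", "g", "m", "n", "s", "z", "f", "v", "r", "l",
    "a", "e", "i", "o", "u"
  )
}

is_vowel <- function(seg) seg %in% c("a", "e", "i", "o", "u", "y", "ə")

#' Generate a canonical synthetic lexicon
#'
#' Builds one canonical speaker's corpus: `n_words` distinct CV-structured
#' words over `inventory`, with word lengths uniform on `length_range` and
#' Zipf-distributed frequencies (`frequency` proportional to
#' `rank^-zipf_exponent`; exponent 0 gives equal frequencies). Fully
#' reproducible under a fixed `seed`.
#'
#' @param n_words Number of distinct meanings (>= 1).
#' @param inventory Segment inventory (>= 3 segments).
#' @param length_range Length-2 integer range of word lengths (segments).
#' @param zipf_exponent Zipf exponent for the frequency distribution.
#' @param seed RNG seed.
#' @param speaker Speaker id of the canonical variety.
#' @return A corpus tibble (`speaker`, `outcome`, `pronunciation`,
#'   `frequency`), meanings labelled `w01`, `w02`, ...
#' @export
generate_lexicon <- function(n_words = 55, inventory = default_inventory(),
                             length_range = c(2, 7), zipf_exponent = 1,
                             seed = NULL, speaker = "canonical") {
  if (n_words < 1L) rlang::abort("`n_words` must be >= 1.")
  if (length(inventory) < 3L) rlang::abort("`inventory` needs at least 3 segments.")
  gen <- function() {
    vows <- inventory[is_vowel(inventory)]
    cons <- setdiff(inventory, vows)
    if (length(vows) == 0L || length(cons) == 0L) {
      # degenerate inventory: fall back to unconstrained draws
      vows <- cons <- inventory
    }
    words <- character(0)
    attempts <- 0L
    while (length(words) < n_words) {
      attempts <- attempts + 1L
      if (attempts > 50L * n_words) {
        rlang::abort("inventory too small for the requested number of distinct words.")
      }
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      start_c <- stats::runif(1) < 0.7
      w <- vapply(seq_len(len), function(p) {
        consonant <- xor(p %% 2L == 1L, !start_c)
        if (consonant) sample(cons, 1L) else sample(vows, 1L)
      }, character(1))
      w <- paste0(w, collapse = "")
      if (!w %in% words) words <- c(words, w)
    }
    rank <- seq_len(n_words)
    freq <- 1e4 * rank^(-zipf_exponent)
    tibble::tibble(
      speaker = speaker,
      outcome = sprintf("w%02d", rank),
      pronunciation = words,
      frequency = freq
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Perturb a canonical corpus into a new synthetic speaker
#'
#' Applies independent per-segment edits to every word: deletion with
#' probability `del_rate`, otherwise substitution with probability
#' `sub_rate` (via `confusion`), and insertion of a uniform inventory
#' segment after each position with probability `ins_rate`. Words are
#' redrawn if all their segments would be deleted, so transcriptions are
#' never empty. A model with all-zero rates returns transcription-identical
#' records under the new speaker id.
#'
#' The default confusion map sends a segment to one of its ring neighbours
#' in the sorted corpus inventory, a deterministic stand-in for phonetic
#' similarity; a named character vector gives a fixed segment-to-segment
#' map instead.
#'
#' @param corpus Canonical corpus tibble.
#' @param sub_rate,ins_rate,del_rate Edit rates in \[0, 1\].
#' @param confusion `NULL` for the ring default, or a named character
#'   vector mapping segments to replacements.
#' @param speaker Id of the generated speaker.
#' @param seed RNG seed.
#' @param diacritics Segmentation mode used when editing.
#' @return A corpus tibble for the perturbed speaker (same outcomes and
#'   frequencies).
#' @export
perturb_speaker <- function(corpus, sub_rate = 0, ins_rate = 0, del_rate = 0,
                            confusion = NULL, speaker = "perturbed",
                            seed = NULL, diacritics = c("keep", "strip")) {
  diacritics <- rlang::arg_match(diacritics)
  validate_corpus(corpus)
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(rates) | rates < 0 | rates > 1)) {
    rlang::abort("edit rates must lie in [0, 1].")
  }
  out <- corpus
  out$speaker <- speaker
  if (all(rates == 0)) {
    return(out)
  }
  segs <- ipa_segment_list(corpus$pronunciation, diacritics = diacritics)
  inventory <- sort(unique(unlist(segs)), method = "radix")
  substitute_seg <- function(s) {
    if (!is.null(confusion)) {
      if (s %in% names(confusion)) confusion[[s]] else s
    } else {
      i <- match(s, inventory)
      k <- length(inventory)
      nb <- c(inventory[(i - 2L) %% k + 1L], inventory[i %% k + 1L])
      sample(nb, 1L)
    }
  }
  edit_word <- function(w) {
    repeat {
      res <- character(0)
      for (s in w) {
        if (stats::runif(1) < del_rate) {
          # deleted
        } else if (stats::runif(1) < sub_rate) {
          res <- c(res, substitute_seg(s))
        } else {
          res <- c(res, s)
        }
        if (stats::runif(1) < ins_rate) {
          res <- c(res, sample(inventory, 1L))
        }
      }
      if (length(res) > 0L) return(res)
    }
  }
  gen <- function() {
    vapply(segs, function(w) render_ipa(edit_word(w)), character(1))
  }
  out$pronunciation <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out
}

#' Generate synthetic Likert ratings from true distances
#'
#' Emulates a panel of raters judging native-likeness: the expected rating
#' is a monotone decreasing linear map from the distance range onto the
#' rating scale (smallest distance = top of the scale), each rater adds
#' Gaussian noise with sd `noise_sd`, and scores are rounded and clipped
#' to the scale.
#'
#' @param distances Tibble with a sample id column (first character
#'   column, e.g. `speaker`) and a `distance`/`mean_distance` column, or a
#'   named numeric vector.
#' @param noise_sd Rater noise standard deviation (rating units).
#' @param scale Length-2 inclusive rating bounds (default 1--7).
#' @param n_raters Number of raters (>= 1).
#' @param seed RNG seed.
#' @return Ratings tibble `rater`, `sample`, `score`.
#' @export
generate_ratings <- function(distances, noise_sd = 0.5, scale = c(1, 7),
                             n_raters = 10, seed = NULL) {
  if (is.numeric(distances) && !is.null(names(distances))) {
    distances <- tibble::tibble(speaker = names(distances), distance = unname(distances))
  }
  dist_col <- if ("distance" %in% names(distances)) "distance" else "mean_distance"
  if (!dist_col %in% names(distances)) {
    rlang::abort("`distances` needs a `distance` or `mean_distance` column.")
  }
  d <- distances[[dist_col]]
  ids <- distances[[1]]
  if (length(d) == 0L) rlang::abort("`distances` is empty.")
  if (n_raters < 1L) rlang::abort("`n_raters` must be >= 1.")
  rng <- range(d)
  expected <- if (diff(rng) > 0) {
    scale[2] - (d - rng[1]) / diff(rng) * (scale[2] - scale[1])
  } else {
    rep(scale[2], length(d))
  }
  gen <- function() {
    dplyr::bind_rows(lapply(seq_len(n_raters), function(rt) {
      noise <- if (noise_sd > 0) stats::rnorm(length(d), sd = noise_sd) else 0
      score <- pmin(scale[2], pmax(scale[1], round(expected + noise)))
      tibble::tibble(rater = sprintf("r%02d", rt), sample = ids, score = score)
    }))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
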