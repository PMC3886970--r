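#' Baseline activation profile over a reference corpus
#'
#' The baseline represents what the listener model hears from an "average"
#' reference speaker: for every outcome, token activations are averaged
#' within each speaker first (repeated words), then across speakers, so a
#' speaker with many tokens of one word does not dominate.
#'
#' @inheritParams token_activations
#' @param reference_corpus Corpus tibble of the reference speakers.
#' @return Tibble with columns `outcome`, `activation` (one row per
#'   outcome occurring in the reference corpus).
#' @export
baseline_profile <- function(weights, reference_corpus, n = NULL,
                             diacritics = NULL, digraphs = NULL) {
  scored <- token_activations(weights, reference_corpus,
    n = n, diacritics = diacritics, digraphs = digraphs
  )
  scored |>
    dplyr::group_by(.data$speaker, .data$outcome) |>
    dplyr::summarise(activation = mean(.data$activation), .groups = "drop") |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(activation = mean(.data$activation), .groups = "drop")
}

#' Per-speaker NDL pronunciation distances against a baseline
#'
#' For each speaker: activations of the listener model for the speaker's
#' tokens, token-averaged per outcome, are compared with the baseline
#' profile. The per-outcome difference is `baseline - speaker` (signed
#' mode, the default: foreign cues can only fail to add association, so
#' positive values mean "further from the baseline") or its absolute value.
#' The speaker's distance is the mean difference over covered outcomes.
#' Baseline outcomes the speaker never produced are skipped with a warning,
#' not scored.
#'
#' @inheritParams token_activations
#' @param baseline Tibble from [baseline_profile()].
#' @param corpus Corpus tibble of speakers to score.
#' @param mode `"signed"` or `"absolute"`.
#' @param detail If `TRUE`, return the per-outcome differences instead of
#'   per-speaker aggregates.
#' @return Tibble `speaker`, `distance`, `n_outcomes` (or, with
#'   `detail = TRUE`: `speaker`, `outcome`, `baseline`, `activation`,
#'   `difference`).
#' @export
speaker_distances <- function(weights, baseline, corpus,
                              mode = c("signed", "absolute"),
                              n = NULL, diacritics = NULL, digraphs = NULL,
                              detail = FALSE) {
  mode <- rlang::arg_match(mode)
  scored <- token_activations(weights, corpus,
    n = n, diacritics = diacritics, digraphs = digraphs
  )
  per_outcome <- scored |>
    dplyr::group_by(.data$speaker, .data$outcome) |>
    dplyr::summarise(activation = mean(.data$activation), .groups = "drop")
  missed <- per_outcome |>
    dplyr::distinct(.data$speaker) |>
    tidyr::crossing(outcome = baseline$outcome) |>
    dplyr::anti_join(per_outcome, by = c("speaker", "outcome"))
  if (nrow(missed) > 0L) {
    rlang::warn(sprintf(
      "%d speaker/outcome pair(s) missing from the test corpus were skipped.",
      nrow(missed)
    ))
  }
  joined <- per_outcome |>
    dplyr::inner_join(
      dplyr::rename(baseline, baseline = "activation"),
      by = "outcome"
    ) |>
    dplyr::mutate(difference = .data$baseline - .data$activation)
  if (mode == "absolute") joined$difference <- abs(joined$difference)
  if (nrow(joined) == 0L) {
    rlang::abort("no outcome is shared between the baseline and the test corpus.")
  }
  if (detail) {
    return(dplyr::select(
      joined, "speaker", "outcome", "baseline", "activation", "difference"
    ))
  }
  joined |>
    dplyr::group_by(.data$speaker) |>
    dplyr::summarise(
      distance = mean(.data$difference),
      n_outcomes = dplyr::n(),
      .groups = "drop"
    )
}

#' Accent distances against a resampled native-listener baseline
#'
#' Repeats the listener-model construction `n_reps` times: in each
#' repetition, about half of the reference (native) speakers are sampled
#' without replacement to train the listener, the remaining reference
#' speakers form the baseline profile, and every speaker in the corpus is
#' scored against that baseline. Resampling averages out the influence of
#' any particular training sample. Results are bit-reproducible for a
#' fixed `seed`.
#'
#' @param corpus Full corpus (reference and test speakers).
#' @param reference_speakers Character vector of reference speaker ids
#'   (at least 2, all present in `corpus`).
#' @param n,diacritics,digraphs Cue-extraction settings.
#' @param n_reps Number of resampling repetitions.
#' @param train_fraction Fraction of reference speakers used to train the
#'   listener in each repetition (`ceiling(train_fraction * N)` speakers;
#'   e.g. 115 reference speakers at 0.5 give 58 training and 57 baseline).
#' @param mode Passed to [speaker_distances()].
#' @param seed RNG seed governing all repetitions.
#' @return Tibble `speaker`, `mean_distance`, `sd_distance`, `n_reps`.
#' @export
accent_distances <- function(corpus, reference_speakers,
                             n = 3, diacritics = c("strip", "keep"),
                             digraphs = NULL, n_reps = 100,
                             train_fraction = 0.5,
                             mode = c("signed", "absolute"), seed = NULL) {
  diacritics <- rlang::arg_match(diacritics)
  mode <- rlang::arg_match(mode)
  validate_corpus(corpus)
  reference_speakers <- unique(reference_speakers)
  if (!all(reference_speakers %in% corpus$speaker)) {
    rlang::abort("every reference speaker must occur in `corpus`.")
  }
  if (length(reference_speakers) < 2L) {
    rlang::abort("at least 2 reference speakers are needed to split into training and baseline.")
  }
  if (n_reps < 1L) rlang::abort("`n_reps` must be >= 1.")
  n_train <- ceiling(train_fraction * length(reference_speakers))
  if (n_train < 1L || n_train >= length(reference_speakers)) {
    rlang::abort("`train_fraction` must leave at least one speaker on each side of the split.")
  }
  run <- function() {
    reps <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      train_ids <- sample(reference_speakers, n_train)
      base_ids <- setdiff(reference_speakers, train_ids)
      fit <- ndl_train(corpus[corpus$speaker %in% train_ids, , drop = FALSE],
        n = n, diacritics = diacritics, digraphs = digraphs
      )
      base <- suppressWarnings(
        baseline_profile(fit, corpus[corpus$speaker %in% base_ids, , drop = FALSE])
      )
      d <- suppressWarnings(speaker_distances(fit, base, corpus, mode = mode))
      d$rep <- r
      reps[[r]] <- d
    }
    dplyr::bind_rows(reps)
  }
  all_reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  all_reps |>
    dplyr::group_by(.data$speaker) |>
    dplyr::summarise(
      mean_distance = mean(.data$distance),
      sd_distance = if (dplyr::n() > 1L) stats::sd(.data$distance) else NA_real_,
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Asymmetric dialect-to-dialect pronunciation distances
#'
#' For every variety i, a listener model is trained on variety i's own
#' pronunciations and its baseline is variety i's own activation profile.
#' Cell (i, j) is the aggregate activation difference when that listener
#' hears variety j. The diagonal is exactly 0 (a listener hearing its own
#' training speech reproduces its baseline), and the matrix is in general
#' asymmetric: comprehension depends on the listener's experience.
#'
#' @param corpus Corpus tibble; `variety_col` labels the varieties
#'   (default: each speaker is its own variety, as when one speaker
#'   represents one dialect).
#' @param variety_col Name of the corpus column holding variety labels.
#' @param n,diacritics,digraphs Cue-extraction settings.
#' @param mode Passed to [speaker_distances()].
#' @return Tibble of class `ndl_dist_tbl` with columns `listener`,
#'   `speaker`, `distance` (all ordered variety pairs, diagonal included
#'   as 0).
#' @export
dialect_distances <- function(corpus, variety_col = "speaker",
                              n = 3, diacritics = c("strip", "keep"),
                              digraphs = NULL, mode = c("signed", "absolute")) {
  diacritics <- rlang::arg_match(diacritics)
  mode <- rlang::arg_match(mode)
  validate_corpus(corpus)
  if (!variety_col %in% names(corpus)) {
    rlang::abort(sprintf("column '%s' not found in corpus.", variety_col))
  }
  varieties <- sort(unique(corpus[[variety_col]]), method = "radix")
  if (length(varieties) < 2L) rlang::abort("at least 2 varieties are required.")
  rows <- list()
  for (vi in varieties) {
    own <- corpus[corpus[[variety_col]] == vi, , drop = FALSE]
    fit <- ndl_train(own, n = n, diacritics = diacritics, digraphs = digraphs)
    base <- baseline_profile(fit, own)
    for (vj in varieties) {
      if (vj == vi) {
        d <- 0
      } else {
        other <- corpus[corpus[[variety_col]] == vj, , drop = FALSE]
        prof <- suppressWarnings(
          tryCatch(baseline_profile(fit, other), error = function(e) NULL)
        )
        if (is.null(prof)) {
          rlang::abort(sprintf(
            "varieties '%s' and '%s' share no outcome known to the listener model.",
            vi, vj
          ))
        }
        cmp <- dplyr::inner_join(
          dplyr::rename(base, baseline = "activation"), prof,
          by = "outcome"
        )
        diff <- cmp$baseline - cmp$activation
        if (mode == "absolute") diff <- abs(diff)
        d <- mean(diff)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        listener = vi, speaker = vj, distance = d
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ndl_dist_tbl", class(out))
  out
}

#' Square matrix view of dialect distances
#'
#' @param distances `ndl_dist_tbl` from [dialect_distances()] (or any
#'   tibble with `listener`, `speaker`, `distance`).
#' @return Numeric matrix, rows = listeners, columns = speakers, zero
#'   diagonal.
#' @export
dialect_matrix <- function(distances) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(distances[c("listener", "speaker", "distance")]),
    names_from = "speaker", values_from = "distance"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$listener
  m[rownames(m), , drop = FALSE]
}

#' Log-transform pronunciation distances
#'
#' Perceptual ratings tend to relate logarithmically to activation-based
#' distances, so correlations are usually reported for both raw and
#' log-transformed distances. Exact zeros (self-distances) have no
#' logarithm; they are either dropped (`NA`, with a message) or offset by
#' a documented epsilon.
#'
#' @param x Non-negative numeric distances.
#' @param zeros `"drop"` (zeros become `NA`) or `"epsilon"` (log of
#'   `x + epsilon`).
#' @param epsilon Offset used when `zeros = "epsilon"`.
#' @param base Logarithm base; correlation is invariant to this choice.
#' @return Numeric vector of transformed distances.
#' @export
log_distance <- function(x, zeros = c("drop", "epsilon"), epsilon = 1e-6,
                         base = exp(1)) {
  zeros <- rlang::arg_match(zeros)
  if (any(x < 0, na.rm = TRUE)) rlang::abort("distances must be non-negative.")
  if (zeros == "epsilon") {
    return(log(x + epsilon, base = base))
  }
  nz <- sum(x == 0, na.rm = TRUE)
  if (nz > 0) {
    rlang::inform(sprintf("log_distance: %d zero distance(s) dropped (NA).", nz))
  }
  out <- ifelse(x == 0, NA_real_, log(x, base = base))
  out
}
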