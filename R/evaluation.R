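#' Mean rating per sample
#'
#' @param ratings Tibble with `rater`, `sample`, `score` (see
#'   [read_ratings()]).
#' @return Tibble `sample`, `mean_rating`, `n_ratings`.
#' @export
mean_ratings <- function(ratings) {
  if (!all(c("rater", "sample", "score") %in% names(ratings))) {
    rlang::abort("`ratings` needs columns rater, sample, score.")
  }
  ratings |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      mean_rating = mean(.data$score),
      n_ratings = dplyr::n(),
      .groups = "drop"
    )
}

#' Pearson product-moment correlation
#'
#' Thin validated front-end to [stats::cor()]: requires equal lengths of
#' at least 3 complete pairs and non-zero variance on both sides.
#'
#' @param x,y Numeric vectors (NA pairs are dropped).
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) rlang::abort("need at least 3 complete pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("zero variance: correlation undefined.")
  }
  stats::cor(x, y)
}

#' Cronbach's alpha over a rater-by-sample ratings table
#'
#' Inter-rater consistency: `alpha = k/(k-1) * (1 - sum(var_i)/var_total)`
#' with raters as items, equivalently computed from the rater covariance
#' matrix as `k/(k-1) * (1 - tr(S)/sum(S))`. Raters typically judge only a
#' subset of samples; with `policy = "pairwise"` (default) the covariance
#' matrix uses pairwise-complete observations, with `"complete"` only
#' samples every rater judged.
#'
#' @param ratings Long tibble `rater`, `sample`, `score`.
#' @param policy `"pairwise"` or `"complete"` missing-data handling.
#' @return Alpha coefficient (a single number).
#' @export
cronbach_alpha <- function(ratings, policy = c("pairwise", "complete")) {
  policy <- rlang::arg_match(policy)
  wide <- ratings |>
    dplyr::group_by(.data$sample, .data$rater) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "rater", values_from = "score")
  m <- as.matrix(wide[-1])
  k <- ncol(m)
  if (k < 2L) rlang::abort("Cronbach's alpha needs at least 2 raters.")
  s <- stats::cov(m, use = if (policy == "pairwise") "pairwise.complete.obs" else "complete.obs")
  if (any(is.na(s))) {
    rlang::abort("covariance undefined: some rater pairs share fewer than 2 samples.")
  }
  k / (k - 1) * (1 - sum(diag(s)) / sum(s))
}

#' Agreement of individual raters with the consensus
#'
#' Correlates each rater's scores with the mean rating of the samples they
#' judged. With `leave_one_out = TRUE` (default) the rater's own scores
#' are excluded from the consensus they are compared against.
#'
#' @param ratings Long tibble `rater`, `sample`, `score`.
#' @param leave_one_out Exclude the rater from the consensus mean.
#' @param min_samples Minimum commonly rated samples per rater.
#' @return Tibble `rater`, `r`, `n_samples` (raters below `min_samples` or
#'   with degenerate variance are dropped).
#' @export
rater_agreement <- function(ratings, leave_one_out = TRUE, min_samples = 3L) {
  raters <- unique(ratings$rater)
  rows <- lapply(raters, function(rt) {
    own <- ratings[ratings$rater == rt, , drop = FALSE]
    others <- if (leave_one_out) ratings[ratings$rater != rt, , drop = FALSE] else ratings
    consensus <- mean_ratings(others)
    joined <- dplyr::inner_join(own, consensus, by = "sample")
    if (nrow(joined) < min_samples) return(NULL)
    r <- tryCatch(pearson(joined$score, joined$mean_rating), error = function(e) NA_real_)
    if (is.na(r)) return(NULL)
    tibble::tibble(rater = rt, r = r, n_samples = nrow(joined))
  })
  dplyr::bind_rows(rows)
}

#' Compare pronunciation distances with perceptual ratings
#'
#' Joins per-sample mean ratings with computed distances and reports the
#' Pearson correlation on raw and log-transformed distances (the two
#' differ: the log is not affine), plus rating reliability when several
#' raters are present.
#'
#' @param distances Tibble with a speaker/sample id column and a
#'   `distance` column (e.g. from [speaker_distances()] or
#'   [accent_distances()]; `mean_distance` is used if present).
#' @param ratings Long ratings tibble `rater`, `sample`, `score`.
#' @param id_col Column of `distances` matching the ratings' `sample`.
#' @param zeros Zero handling for [log_distance()].
#' @return One-row tibble: `n`, `r_raw`, `r_log`, `alpha`.
#' @export
evaluate_distances <- function(distances, ratings, id_col = "speaker",
                               zeros = c("drop", "epsilon")) {
  zeros <- rlang::arg_match(zeros)
  dist_col <- if ("distance" %in% names(distances)) "distance" else "mean_distance"
  if (!dist_col %in% names(distances)) {
    rlang::abort("`distances` needs a `distance` or `mean_distance` column.")
  }
  d <- tibble::tibble(
    sample = distances[[id_col]],
    distance = distances[[dist_col]]
  )
  joined <- dplyr::inner_join(mean_ratings(ratings), d, by = "sample")
  if (nrow(joined) < 3L) rlang::abort("fewer than 3 samples have both a rating and a distance.")
  r_raw <- pearson(joined$mean_rating, joined$distance)
  logd <- suppressMessages(log_distance(joined$distance, zeros = zeros))
  r_log <- tryCatch(pearson(joined$mean_rating, logd), error = function(e) NA_real_)
  alpha <- tryCatch(cronbach_alpha(ratings), error = function(e) NA_real_)
  tibble::tibble(
    n = nrow(joined), r_raw = r_raw, r_log = r_log, alpha = alpha
  )
}
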