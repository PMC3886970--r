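#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of learned association strengths
#'
#' @param object An `ndl_fit`.
#' @param max_cues Show at most this many cues (those with the largest
#'   absolute weight), keeping the panel readable for big cue registries.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ndl_fit
#' @export
autoplot.ndl_fit <- function(object, max_cues = 40, ...) {
  td <- tidy(object)
  keep <- td |>
    dplyr::group_by(.data$cue) |>
    dplyr::summarise(m = max(abs(.data$weight)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = max_cues)
  td <- dplyr::semi_join(td, keep, by = "cue")
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$outcome, y = .data$cue, fill = .data$weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(
      x = "outcome", y = "cue", fill = "association",
      title = "Cue-outcome association strengths"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of an asymmetric dialect distance matrix
#'
#' @param object An `ndl_dist_tbl` from [dialect_distances()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ndl_dist_tbl
#' @export
autoplot.ndl_dist_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$speaker, y = .data$listener, fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(
      x = "speaker (heard variety)", y = "listener (trained variety)",
      fill = "distance", title = "NDL pronunciation distances"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of distances against mean perceptual ratings
#'
#' @param distances Tibble with an id column and `distance` /
#'   `mean_distance`.
#' @param ratings Long ratings tibble `rater`, `sample`, `score`.
#' @param id_col Distance column matching the ratings' `sample`.
#' @param log_x Plot the distance axis on a log scale.
#' @return A ggplot object.
#' @export
plot_distance_ratings <- function(distances, ratings, id_col = "speaker",
                                  log_x = FALSE) {
  dist_col <- if ("distance" %in% names(distances)) "distance" else "mean_distance"
  d <- tibble::tibble(
    sample = distances[[id_col]], distance = distances[[dist_col]]
  )
  joined <- dplyr::inner_join(mean_ratings(ratings), d, by = "sample")
  p <- ggplot2::ggplot(joined, ggplot2::aes(
    x = .data$distance, y = .data$mean_rating
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "NDL pronunciation distance", y = "mean rating",
      title = "Perceptual validation"
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}
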