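#' Plot spatial information scores by relation
#'
#' One point per subject with the group mean and its standard error,
#' faceted by label mode when both are present.
#'
#' @param object An `rsa_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsa_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$relation, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, colour = "firebrick",
                          linewidth = 0.8) +
    ggplot2::facet_wrap(~label_mode) +
    ggplot2::labs(x = NULL, y = "spatial information score (Fisher z)") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed neural space against the physical layout
#'
#' @param x A `neural_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_neural_space <- function(x, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(which = "neural", loc = paste0("Loc", 1:4),
                   x = x$coords[, 1], y = x$coords[, 2]),
    tibble::tibble(which = "physical", loc = paste0("Loc", 1:4),
                   x = physical_layout(2)[, 1], y = physical_layout(2)[, 2]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$loc), vjust = -1,
                       show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "axis 1 (m)", y = "axis 2 (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot partition scores against empirical chance
#'
#' @param object A `partition_scores` result.
#' @param chance Optional tibble from [empirical_chance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partition_scores <- function(object, chance = NULL, ...) {
  mean_scores <- object$scores |>
    dplyr::group_by(.data$bin, .data$relation) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  p <- ggplot2::ggplot(mean_scores,
                       ggplot2::aes(x = factor(.data$bin), y = .data$score,
                                    group = .data$relation,
                                    colour = .data$relation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "adaptation-ranked voxel bin (low to high)",
                  y = "spatial information score", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    ch <- chance |>
      dplyr::group_by(.data$bin, .data$relation) |>
      dplyr::summarise(chance_score = mean(.data$chance_score),
                       .groups = "drop")
    p <- p + ggplot2::geom_line(
      data = ch, ggplot2::aes(y = .data$chance_score), linetype = 3)
  }
  p
}

#' Plot the long-axis decile profile of spatial information scores
#'
#' @param object An `axis_profile` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.axis_profile <- function(object, ...) {
  mean_scores <- object$scores |>
    dplyr::group_by(.data$decile, .data$relation) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  ggplot2::ggplot(mean_scores,
                  ggplot2::aes(x = .data$decile, y = .data$score,
                               colour = .data$relation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "ROI long-axis decile (anterior to posterior)",
                  y = "spatial information score", colour = NULL) +
    ggplot2::theme_minimal()
}
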