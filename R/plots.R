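#' Heatmap of state centroids
#'
#' Regions by state, tile colour = centroid loading. Positive loadings mark
#' the phase community that detaches from the global mode.
#'
#' @param object A `leida_states` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.leida_states <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = factor(.data$state),
      y = factor(.data$region, levels = rev(unique(.data$region))),
      fill = .data$loading
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "state", y = NULL, fill = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Violin plots of occupancy and lifetime by group
#'
#' @param metrics_tbl Long metrics table from [cohort_metrics()] with a
#'   `group` column.
#' @return A ggplot object.
#' @export
plot_state_metrics <- function(metrics_tbl) {
  stopifnot("group" %in% names(metrics_tbl))
  metrics_tbl |>
    filter(.data$metric %in% c("occupancy", "lifetime"), !is.na(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$state), y = .data$value,
                                 fill = .data$group)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(0.8),
                         alpha = 0.6, scale = "width") +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                          width = 0.15, outlier.shape = NA) +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "state", y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of group differences in transition probabilities
#'
#' Tile colour = difference of group mean switch-conditional transition
#' probabilities (first group minus second, alphabetically); asterisks mark
#' uncorrected p < 0.05 in the exploratory ANCOVA.
#'
#' @param stats A `leida_stats` object from [run_stats_battery()].
#' @return A ggplot object.
#' @export
plot_transition_differences <- function(stats) {
  stopifnot(inherits(stats, "leida_stats"))
  d <- stats$transitions |>
    mutate(delta = .data$mean_1 - .data$mean_2,
           sig = ifelse(.data$p < 0.05, "*", ""))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$to), y = factor(.data$from),
                                  fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig)) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "to state", y = "from state",
      fill = sprintf("%s - %s", stats$groups[1], stats$groups[2])
    ) +
    ggplot2::theme_minimal()
}

#' Dunn-index model-selection curve
#'
#' @param solution A `leida_states` returned by [select_k()] (carries the
#'   sweep table).
#' @return A ggplot object.
#' @export
plot_k_sweep <- function(solution) {
  stopifnot(inherits(solution, "leida_states"), !is.null(solution$sweep))
  ggplot2::ggplot(solution$sweep, ggplot2::aes(x = .data$k, y = .data$dunn)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = solution$sweep[which.max(solution$sweep$dunn), ],
                        colour = "#B2182B", size = 3) +
    ggplot2::labs(x = "number of states k", y = "Dunn index") +
    ggplot2::theme_minimal()
}
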