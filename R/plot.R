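# ggplot2 views of partitions and selection trajectories.

#' Plot marker effects along the genome, colored by origin class
#'
#' @param partition An [partition_effects()] result.
#' @param map Optional [genetic_map()]; when given, effects are plotted
#'   against cM position faceted by chromosome, otherwise against marker
#'   index.
#' @return A ggplot object.
#' @export
plot_effect_partition <- function(partition, map = NULL) {
  df <- tibble::as_tibble(partition)
  if (!is.null(map)) {
    df <- dplyr::inner_join(df, genetic_map(map), by = "marker")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cM, y = .data$effect,
                                          colour = .data$class)) +
      ggplot2::facet_wrap(~chromosome, nrow = 1, scales = "free_x")
  } else {
    df$index <- seq_len(nrow(df))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$effect,
                                          colour = .data$class))
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(P = "#c0392b", S = "#27ae60", Z = "grey70")) +
    ggplot2::labs(y = "marker effect", colour = "favorable\norigin") +
    ggplot2::theme_minimal()
}

#' Compare the absolute-effect distributions of the two origins
#'
#' Histograms of `|effect|` for the primary (`P`) and secondary (`S`)
#' marker classes, the distributions contrasted by
#' [ks_compare_effects()].
#'
#' @param partition An [partition_effects()] result.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_effect_distributions <- function(partition, bins = 30) {
  df <- dplyr::filter(tibble::as_tibble(partition), .data$class %in% c("P", "S"))
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$effect), fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.55) +
    ggplot2::scale_fill_manual(values = c(P = "#c0392b", S = "#27ae60")) +
    ggplot2::labs(x = "|marker effect|", fill = "favorable\norigin") +
    ggplot2::theme_minimal()
}

#' @describeIn run_recurrent_selection Plot replicate-mean trajectories of
#'   the outcome metrics (`mu_BV`, `mu_P`, `mu_S`) by cycle and method.
#' @param object An `osgs_metrics` tibble.
#' @param ... Unused.
#' @method autoplot osgs_metrics
#' @export
autoplot.osgs_metrics <- function(object, ...) {
  df <- dplyr::group_by(tibble::as_tibble(object), .data$cycle, .data$method)
  df <- dplyr::summarise(df,
    dplyr::across(c("mu_BV", "mu_P", "mu_S"), mean), .groups = "drop")
  df <- tidyr::pivot_longer(df, c("mu_BV", "mu_P", "mu_S"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "selection cycle", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
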