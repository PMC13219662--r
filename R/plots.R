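#' Plot individual load components
#'
#' Boxplots of per-individual masked (heterozygous) and realized
#' (homozygous-derived) counts by population, one panel per mutation
#' class and component.
#'
#' @param load Tibble from [individual_load()].
#' @return A ggplot object.
#' @export
plot_load <- function(load) {
  long <- tidyr::pivot_longer(load, c("masked", "realized"),
                              names_to = "component", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population,
                                     y = .data$count,
                                     fill = .data$population)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_grid(component ~ class, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "genotype count") +
    ggplot2::theme_minimal()
}

#' Plot F_ROH per individual
#'
#' @param froh_tab Tibble from [froh()], optionally with a
#'   `population` column.
#' @return A ggplot object.
#' @export
plot_froh <- function(froh_tab) {
  x_var <- if ("population" %in% names(froh_tab)) "population" else "sample"
  ggplot2::ggplot(froh_tab,
                  ggplot2::aes(x = .data[[x_var]], y = .data$froh)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1,
                                                            height = 0)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}

#' Plot a recent-Ne trajectory
#'
#' Effective population size per ROH-length epoch against the epoch age.
#'
#' @param traj Tibble from [ne_trajectory()], optionally with a
#'   `population` column.
#' @return A ggplot object.
#' @export
plot_ne_trajectory <- function(traj) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$age_years,
                                          y = .data$ne))
  if ("population" %in% names(traj)) {
    p <- p + ggplot2::aes(colour = .data$population)
  }
  p +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "years before present", y = "Ne") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.purging_summary
#' @param object A `purging_summary`.
#' @method autoplot purging_summary
#' @export
autoplot.purging_summary <- function(object, ...) {
  ggplot2::ggplot(object$reductions,
                  ggplot2::aes(x = .data$class,
                               y = .data$percent_reduction,
                               fill = .data$focal)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% reduction vs reference",
                  fill = "focal population") +
    ggplot2::theme_minimal()
}

#' @rdname tidy.ibs_dist
#' @param object An `ibs_dist`.
#' @method autoplot ibs_dist
#' @export
autoplot.ibs_dist <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample1, y = .data$sample2,
                               fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - IBS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
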