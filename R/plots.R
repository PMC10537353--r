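#' Bubble plot of a floral calendar
#'
#' The standard way to look at a flowering semester: one row per plant, one
#' column per week, with bubble area proportional to the flower-bud count.
#' Zero weeks are left blank.
#'
#' @param object A [floral_calendar].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot floral_calendar
#' @export
autoplot.floral_calendar <- function(object, ...) {
  long <- as_tibble(object) %>% dplyr::filter(.data$count > 0)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$week, y = .data$plant_id, size = .data$count
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(limits = c(1, object$n_weeks)) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(
      title = sprintf(
        "%s / %s (%s) / %s", object$department, object$semester,
        object$flowering_period, object$accession
      ),
      x = "week of semester", y = NULL, size = "buds"
    ) +
    ggplot2::theme_minimal()
}

#' Box plots of a phenological descriptor by department and semester
#'
#' @param descriptors A descriptor table from [descriptor_table()].
#' @param descriptor Which descriptor to plot: `"r_i"`, `"cv_i"` or
#'   `"event"`.
#' @return A ggplot object.
#' @export
plot_descriptors <- function(descriptors,
                             descriptor = c("r_i", "cv_i", "event")) {
  descriptor <- match.arg(descriptor)
  df <- descriptors %>% dplyr::filter(!is.na(.data[[descriptor]]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$department, y = .data[[descriptor]]
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~semester, nrow = 1) +
    ggplot2::labs(x = NULL, y = descriptor) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
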