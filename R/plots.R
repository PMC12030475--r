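#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked-bar view of a CWM variance decomposition
#'
#' @param object A `cwm_decomposition`.
#' @param ... Unused.
#' @return A ggplot: per trait and ANOVA term, the percentage contributions
#'   of turnover, ITV and covariation.
#' @export
autoplot.cwm_decomposition <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$term != "total") |>
    tidyr::pivot_longer(c("turnover_pct", "itv_pct", "cov_pct"),
                        names_to = "component", values_to = "pct") |>
    mutate(component = factor(.data$component,
                              levels = c("turnover_pct", "itv_pct",
                                         "cov_pct"),
                              labels = c("turnover", "ITV", "covariation")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$pct,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = NULL, y = "% of total specific SS", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot community-weighted means by climate and treatment
#'
#' @param cwm A CWM table from [cwm_table()].
#' @param design The plot design.
#' @param convention Which convention to display (default `"specific"`).
#' @return A ggplot of per-plot CWMs, faceted by trait.
#' @export
plot_cwm <- function(cwm, design, convention = "specific") {
  df <- cwm |>
    filter(.data$convention == !!convention) |>
    inner_join(as_plot_design(design), by = "plot_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$climate, y = .data$value,
                                   colour = .data$treatment)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(y = paste(convention, "CWM"), x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot functional-diversity indices by climate and treatment
#'
#' @param fd A tibble from [fd_indices()].
#' @param design The plot design.
#' @return A ggplot of the four indices per plot.
#' @export
plot_fd <- function(fd, design) {
  df <- fd |>
    select("plot_id", "fric", "feve", "fdiv", "fdis") |>
    tidyr::pivot_longer(-"plot_id", names_to = "index",
                        values_to = "value") |>
    inner_join(as_plot_design(design), by = "plot_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$climate, y = .data$value,
                                   colour = .data$treatment)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
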