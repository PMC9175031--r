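percept_fill <- c(
  GROUPED_H = "#1b9e77", GROUPED_V = "#7570b3", UNGROUPED = "#d95f02",
  UNREPORTED = "grey80", TRANSITION = "black", MIXED = "grey60"
)

#' Plot a percept timeline
#'
#' Draws the labelled partition of a trial as a coloured bar over time,
#' mirroring the logic timing diagrams used to inspect button-box data.
#'
#' @param object A `percept_timeline` (or `latent_timeline`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.percept_timeline <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$t_start, xmax = .data$t_end,
        ymin = 0, ymax = 1, fill = .data$label
      )
    ) +
    ggplot2::scale_fill_manual(values = percept_fill, name = "percept") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.latent_timeline <- autoplot.percept_timeline

#' Dominance-time summary plot
#'
#' Mean exclusive dominance time (with SD error bars) per percept class,
#' condition and group.
#'
#' @param report A `rivalry_report`.
#' @return A ggplot object.
#' @export
plot_dominance_times <- function(report) {
  stopifnot(inherits(report, "rivalry_report"))
  long <- report$dominance_summary |>
    tidyr::pivot_longer(
      -c("group", "condition_id", "n"),
      names_to = c("percept", ".value"), names_pattern = "t_(.*)_(mean|sd)"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$condition_id, y = .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::facet_wrap(~percept) +
    ggplot2::labs(x = NULL, y = "dominance time (s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Epoch-difference boxplot
#'
#' Boxplots of the per-participant difference in mean grouped-dominance
#' epochs between the between- and within-hemifield same-eye conditions,
#' by group; the cross marks the group mean.
#'
#' @param report A `rivalry_report`.
#' @return A ggplot object.
#' @export
plot_epoch_differences <- function(report) {
  stopifnot(inherits(report, "rivalry_report"))
  df <- filter(report$epoch_diff, !is.na(.data$d_epoch))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$d_epoch)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "epoch difference DH - SH (s)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rivalry_report <- function(object, type = c("dominance", "epochs"), ...) {
  type <- match.arg(type)
  switch(type,
    dominance = plot_dominance_times(object),
    epochs = plot_epoch_differences(object)
  )
}
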