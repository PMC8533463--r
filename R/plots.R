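# ggplot2 displays for the main result types.

#' Kaplan-Meier step curves
#'
#' @param object A `km_fit` tibble from [km_curve()].
#' @param ... Unused.
#' @return A ggplot object: one survival step function per group, censoring
#'   marks as ticks.
#' @export
autoplot.km_fit <- function(object, ...) {
  # prepend the (0, 1) anchor per group so the step starts at S(0) = 1
  anchors <- object |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1, n_event = 0L, n_censor = 0L)
  df <- dplyr::bind_rows(anchors, object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$n_censor > 0, , drop = FALSE],
                        shape = 3, size = 2, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "expression") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param de A `de_result` tibble from [call_differential()].
#' @param lfc_threshold,fdr_threshold Guide lines matching the calling
#'   thresholds.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_threshold = 1, fdr_threshold = 0.01) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_threshold, lfc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#0570b0", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn-style cohort-sharing counts
#'
#' @param counts Tibble from [venn_counts()].
#' @return A ggplot object with one bar per cohort-membership class.
#' @export
plot_venn_counts <- function(counts) {
  df <- dplyr::mutate(counts,
                      cohort_set = factor(.data$cohort_set,
                                          levels = rev(counts$cohort_set)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$cohort_set)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = "features", y = "cohort membership") +
    ggplot2::theme_minimal()
}
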