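# ggplot2 helpers for posterior output.

#' Trace and density plot of posterior draws
#'
#' @param object An `nof1_draws` object.
#' @param parameters Optional character vector of parameters to show.
#' @param ... Unused.
#' @return A ggplot object (trace panels per parameter, colored by chain).
#' @export
autoplot.nof1_draws <- function(object, parameters = NULL, ...) {
  df <- as_draws_df(object)
  if (!is.null(parameters)) {
    df <- df[df$parameter %in% parameters, ]
  } else if (length(object$par_names) > 12) {
    df <- df[df$parameter %in% object$par_names[1:12], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$.draw, .data$value,
                                   color = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "draw", y = NULL, color = "chain") +
    ggplot2::theme_minimal()
}

#' Forest plot of effects per individual and pooled
#'
#' Plots posterior medians and credible intervals, one row per individual
#' with the pooled ("All") row emphasized, mirroring the usual presentation
#' of aggregated N-of-1 results.
#'
#' @param summaries Tibble with columns `label`, `median`, `lower`,
#'   `upper` (e.g. built from [summarize_draws()] rows); a row labeled
#'   `"All"` is drawn in a distinct color.
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_forest <- function(summaries, xlab = "treatment difference") {
  summaries$label <- factor(summaries$label,
                            levels = rev(unique(summaries$label)))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$median, .data$label,
                               color = .data$label == "All")) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper),
                             show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c("FALSE" = "black",
                                           "TRUE" = "firebrick")) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}
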