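# ggplot2 displays for the main result types.

#' @rdname nmds
#' @param object A `grazesel_nmds` object.
#' @param groups Optional group labels, one per sample, used for colour.
#' @export
autoplot.grazesel_nmds <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", object$stress),
      x = "NMDS1", y = "NMDS2")
  if (is.null(groups)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group),
                            level = 0.95, na.rm = TRUE)
  }
}

#' Plot per-item selectivity
#'
#' Box plot of Jacobs' D per food item (optionally split by a grouping
#' column such as strategy), with the neutral-selection line at zero:
#' items above it are preferred relative to availability, items below are
#' avoided.
#'
#' @param selectivity Output of [compute_selectivity()] (undefined D rows
#'   are dropped).
#' @param group Optional name of a grouping column in `selectivity`.
#' @return A ggplot object.
#' @export
plot_selectivity <- function(selectivity, group = NULL) {
  require_cols(selectivity, c("item", "d"), "selectivity table")
  df <- selectivity[is.finite(selectivity$d), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$item, .data$d)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Jacobs' D") +
    ggplot2::ylim(-1, 1)
  if (is.null(group)) {
    p + ggplot2::geom_boxplot()
  } else {
    p + ggplot2::geom_boxplot(ggplot2::aes(fill = .data[[group]]))
  }
}

#' Plot standardized effect sizes of a richness regression
#'
#' Dot-and-interval display of the coefficients (intercept omitted) with
#' their confidence intervals.
#'
#' @param object A `grazesel_regression` object.
#' @param ... Unused.
#' @export
autoplot.grazesel_regression <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "Effect size (standardized)", y = NULL)
}

#' Plot a classified behaviour series
#'
#' Epoch-mean ODBA over time coloured by the assigned behaviour, with the
#' classification threshold drawn in.
#'
#' @param series Output of [classify_behavior()].
#' @param threshold Threshold used at classification (drawn as a line).
#' @return A ggplot object.
#' @export
plot_behavior <- function(series, threshold = 0.1) {
  require_cols(series, c("window_start", "odba", "label"), "behaviour series")
  ggplot2::ggplot(series,
                  ggplot2::aes(.data$window_start / 3600, .data$odba,
                               colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "Time (h)", y = "Epoch mean ODBA (g)", colour = NULL)
}
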