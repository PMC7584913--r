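# ggplot2 views of the scan results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the sliding-window cosegregation proportions
#'
#' One panel per scaffold; windows with undefined proportions are omitted.
#'
#' @param object A `coseg_windows` tibble from [window_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coseg_windows <- function(object, ...) {
  d <- object[!is.na(object$proportion), ]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$win_start + .data$win_end) / 2e6,
                                  y = .data$proportion)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(~ .data$scaffold, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "window midpoint (Mb)",
                  y = "proportion cosegregating") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot cosegregating-variant counts per fixed-width bin
#'
#' @param object A `coseg_bins` tibble from [bin_counts()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coseg_bins <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                               y = .data$n_coseg)) +
    ggplot2::geom_col(width = (object$bin_end[1] - object$bin_start[1]) / 1e6,
                      fill = "darkred") +
    ggplot2::facet_grid(~ .data$scaffold, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "cosegregating variants") +
    ggplot2::theme_bw()
}

#' Plot a two-group shape-metric comparison
#'
#' @param object A `shape_comparison` from [compare_shape_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_comparison <- function(object, ...) {
  d <- tibble(
    group = rep(c("a", "b"), c(object$n_a, object$n_b)),
    value = c(object$values_a, object$values_b)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 0.8) +
    ggplot2::labs(y = object$metric, x = NULL) +
    ggplot2::theme_bw()
}
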