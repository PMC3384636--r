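#' Plot a per-residue epitope propensity profile
#'
#' Draws the propensity track along the chain; known epitope intervals can
#' be shaded for comparison, and the 0.5 fragment-decision cutoff is shown
#' as a dashed reference line.
#'
#' @param object An `epitope_profile` from [predict_chain()] or
#'   [read_profile()].
#' @param truth Optional tibble of 1-based inclusive intervals (`start`,
#'   `end`) to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot epitope_profile
#' @export
autoplot.epitope_profile <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$propensity))
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_rect(
      data = truth,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::labs(
      x = "Residue position", y = "Epitope propensity",
      title = attr(object, "id"),
      subtitle = paste0("scheme: ", attr(object, "scheme") %||% "?",
                        if (identical(attr(object, "scheme"), "distance"))
                          paste0(" (k = ", attr(object, "k"), ")"))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.epitope_profile
#' @param profile An `epitope_profile`.
#' @export
plot_profile <- function(profile, truth = NULL) {
  autoplot.epitope_profile(profile, truth = truth)
}
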