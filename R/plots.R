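# ggplot2 visualisations. Colour semantics follow the score classes:
# low in blue, increased in red, high in dark red (emphasised).

CLASS_COLOURS <- c(low = "#2166ac", increased = "#ef3b2c", high = "#99000d")

#' Bar chart of combined scores
#'
#' One bar per sequence in row order, filled by class (low blue, increased
#' red, high dark red), with dashed guides at the low/high thresholds.
#'
#' @param scores A `"prion_scores"` tibble.
#' @param params [combination_params()] for the threshold guides (defaults
#'   to the attribute carried by `scores`).
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, params = attr(scores, "params")) {
  stopifnot(is.data.frame(scores),
            all(c("id", "score", "class") %in% names(scores)))
  if (is.null(params)) params <- combination_params()
  df <- as_tibble(scores)
  df$id <- factor(df$id, levels = unique(df$id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$score,
                                   fill = .data$class)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_hline(yintercept = c(params$theta_low, params$theta_high),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::scale_fill_manual(values = CLASS_COLOURS, drop = FALSE,
                               name = "class") +
    ggplot2::labs(x = NULL, y = "combined aggregation-propensity score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_scores
#' @param object A `"prion_scores"` tibble.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot prion_scores
#' @export
autoplot.prion_scores <- function(object, ...) {
  plot_scores(object)
}

#' Line plot of a windowed profile
#'
#' Plots any per-window track produced by [foldindex_profile()] or
#' [composition_profile()] against the window center, shading windows that
#' pass the disorder gate.
#'
#' @param profile Tibble with columns `center`, `value` and optionally
#'   `disordered`.
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, ylab = "windowed value") {
  stopifnot(is.data.frame(profile),
            all(c("center", "value") %in% names(profile)))
  p <- ggplot2::ggplot(as_tibble(profile),
                       ggplot2::aes(x = .data$center, y = .data$value))
  if ("disordered" %in% names(profile)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$disordered), size = 0.8) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "#2166ac", `FALSE` = "grey60"),
        name = "disordered")
  }
  p + ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "window center (residue)", y = ylab) +
    ggplot2::theme_minimal()
}
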