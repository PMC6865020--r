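#' Heat map of a state-space density
#'
#' Renders the (W, U) frequency distribution with the balanced-state
#' (Schreiber) curve and the `D = 1` regime separator overlaid; W on
#' the horizontal axis, U on the vertical, as is conventional for
#' this state space.
#'
#' @param object A `uw_density` from [state_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uw_density <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$count > 0, ]
  wseq <- seq(0.001, 0.999, length.out = 200)
  curve_df <- data.frame(W = wseq, U = schreiber_curve_u(wseq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w_mid, y = .data$u_mid)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$W, y = .data$U),
                       linewidth = 0.4, colour = "black") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "pixels") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "relative excess water W", y = "relative excess energy U",
                  title = object$stratum) +
    ggplot2::theme_minimal()
}

#' Quadrant-fraction bars for a pipeline result
#'
#' @param object A `uw_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object: quadrant fractions per stratum and
#'   greenness category.
#' @export
autoplot.uw_pipeline <- function(object, ...) {
  df <- object$summary
  df <- df[df$quadrant != "no_change" & !is.na(df$fraction), ]
  pal <- c(Q1_pink = "#e78ac3", Q2_yellow = "#e6c200",
           Q3_lightblue = "#7ec8e3", Q4_darkblue = "#1f4e9c")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$greenness_category,
                                   y = .data$fraction,
                                   fill = .data$quadrant)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::labs(x = "greenness category", y = "quadrant fraction") +
    ggplot2::theme_minimal()
}

#' Scatter of pixel states in (U, W) space
#'
#' @param states Tibble with `U`, `W` (e.g. `pixels` from
#'   [run_pipeline()], or [compute_states()] output), optionally with
#'   a column to colour by.
#' @param colour Optional name of a colour column.
#' @return A ggplot object.
#' @export
plot_state_space <- function(states, colour = NULL) {
  wseq <- seq(0.001, 0.999, length.out = 200)
  curve_df <- data.frame(W = wseq, U = schreiber_curve_u(wseq))
  p <- ggplot2::ggplot(states, ggplot2::aes(x = .data$W, y = .data$U))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.5, alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_point(size = 0.5, alpha = 0.6)
  }
  p +
    ggplot2::geom_line(data = curve_df,
                       ggplot2::aes(x = .data$W, y = .data$U),
                       colour = "black", linewidth = 0.4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "relative excess water W",
                  y = "relative excess energy U") +
    ggplot2::theme_minimal()
}
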